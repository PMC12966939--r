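test_that("z-scores use population sd and guard constant columns", {
  z <- zscore(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  expect_warning(zc <- zscore(cbind(a = c(1, 2, 3), b = c(5, 5, 5))))
  expect_equal(unname(zc[, "b"]), c(0, 0, 0))

  pre <- c(-sqrt(1.5), 0, sqrt(1.5))  # already mean-0, population-sd-1
  expect_equal(as.numeric(zscore(matrix(pre, ncol = 1))), pre, tolerance = 1e-12)

  expect_error(zscore(matrix(1, nrow = 1)), class = "invalid_argument")
})

test_that("z-scores match the closed-form oracle on random matrices", {
  set.seed(101)
  for (i in 1:100) {
    m <- matrix(stats::rnorm(8 * 3, mean = stats::runif(1, -50, 50),
                             sd = stats::runif(1, 0.5, 20)), nrow = 8)
    expect_equal(unname(zscore(m)), unname(zscore_oracle(m)), tolerance = 1e-10)
  }
})

test_that("composite scores rescale to [0, 100] with min-rank ties", {
  z <- zscore(cbind(x = c(1, 2, 3), y = c(10, 30, 20)))
  rownames(z) <- c("A", "B", "C")
  st <- composite_scores(z, c(1, 1))
  expect_equal(unname(st$score), c(0, 100, 100))
  expect_equal(unname(st$rank), c(3L, 1L, 1L))

  # bracketing and order preservation on random non-constant input
  set.seed(202)
  for (i in 1:25) {
    z <- zscore(matrix(stats::rnorm(37 * 4), nrow = 37))
    st <- composite_scores(z)
    expect_equal(min(st$score), 0)
    expect_equal(max(st$score), 100)
    expect_equal(order(st$score), order(st$composite_raw))
  }
})

test_that("single-indicator polarity flip reverses the ranking exactly", {
  z <- zscore(matrix(c(5, 1, 9, 3, 7), ncol = 1,
                     dimnames = list(letters[1:5], "x")))
  up <- composite_scores(z, 1)
  down <- composite_scores(z, -1)
  expect_equal(unname(up$rank), length(up$rank) + 1L - unname(down$rank))
  expect_equal(unname(up$score), unname(100 - down$score))
})

test_that("degenerate all-equal composite yields flat 50 scores", {
  z <- matrix(0, nrow = 3, ncol = 2)
  expect_warning(st <- composite_scores(z))
  expect_equal(unname(st$score), c(50, 50, 50))
})

test_that("pearson correlation matches examples and handles degeneracies", {
  expect_equal(pearson_correlation(1:3, 1:3)$r, 1.0)
  expect_equal(pearson_correlation(1:3, 3:1)$r, -1.0)
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 5))$r, 0.9820,
               tolerance = 1e-4)
  expect_gt(pearson_correlation(1:3, 1:3)$p, 0)
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), class = "degenerate_correlation")
  expect_error(pearson_correlation(1:2, 1:2), class = "invalid_argument")
})

test_that("pearson agrees with the brute-force formula on 100 random vectors", {
  set.seed(303)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- stats::rnorm(n)
    y <- 0.5 * x + stats::rnorm(n)
    got <- pearson_correlation(x, y)
    want <- pearson_oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("Welch test reproduces hand-derived statistic and df", {
  tt <- welch_ttest(c(1, 2, 3), c(2, 4, 6))
  expect_equal(tt$statistic, -1.549, tolerance = 1e-3)
  expect_equal(tt$df, 2.941, tolerance = 1e-3)

  same <- welch_ttest(c(4, 4, 5, 5), c(4, 4, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  swapped <- welch_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(swapped$statistic, -tt$statistic)
  expect_equal(swapped$p, tt$p)

  expect_error(welch_ttest(1, c(2, 3)), class = "invalid_argument")
  expect_error(welch_ttest(c(1, 1), c(2, 2)), class = "degenerate_variance")
})

test_that("paired test reproduces hand-derived values and degenerate cases", {
  tt <- paired_ttest(c(1, 2, 3), c(2, 2, 5))
  expect_equal(tt$statistic, 1.732, tolerance = 1e-3)
  expect_equal(tt$df, 2)

  flat <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  shifted <- paired_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_true(is.infinite(shifted$statistic))
  expect_gt(shifted$p, 0)

  expect_error(paired_ttest(1:3, 1:4), class = "invalid_argument")
})

test_that("correlation matrix covers all unordered pairs symmetrically", {
  clean <- demo_clean()
  cols4 <- names(clean$indicators)[1:4]
  expect_length(correlation_matrix(clean, cols4[1:2]), 1)
  expect_length(correlation_matrix(clean, cols4), 6)

  res <- correlation_matrix(clean, cols4[1:2])[[1]]
  flipped <- pearson_correlation(clean$indicators[[cols4[2]]],
                                 clean$indicators[[cols4[1]]])
  expect_equal(res$r, flipped$r)

  self <- pearson_correlation(clean$indicators[[1]], clean$indicators[[1]])
  expect_equal(self$r, 1)
})

test_that("analyze_table assembles a full bundle from a clean table", {
  bundle <- demo_bundle()
  expect_s3_class(bundle$scores, "score_table")
  expect_equal(bundle$clusters$k, 3L)
  expect_length(bundle$correlations, choose(6, 2))
  expect_length(bundle$tests, 1)
  expect_equal(bundle$tests[[1]]$kind, "paired")
  expect_equal(max(bundle$scores$score), 100)
})
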