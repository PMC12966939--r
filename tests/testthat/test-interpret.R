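fake_scores <- function(units, scores) {
  structure(list(unit_names = units, z_matrix = matrix(0, length(units), 1),
                 composite_raw = scores, score = scores,
                 rank = rank(-scores, ties.method = "min")),
            class = "score_table")
}

fake_corr <- function(r, p, x = "shc_functioning", y = "specialist_doctors") {
  structure(list(var_x = x, var_y = y, r = r, p = p, n = 37L),
            class = "correlation_result")
}

fake_test <- function(p, mean_diff = 0, kind = "paired") {
  structure(list(kind = kind, statistic = 1, df = 36, p = p, n1 = 37L, n2 = 37L,
                 mean_diff = mean_diff), class = "test_result")
}

test_that("ranking statements name top and bottom units, ties alphabetical", {
  st <- interpret_ranking(fake_scores(c("Meghalaya", "Goa", "Bihar"), c(100, 40, 0)))
  expect_equal(st[[1]]$text, "Meghalaya recorded the highest composite score (100.0).")
  expect_match(st[[2]]$text, "^Bihar recorded the lowest")

  tied <- interpret_ranking(fake_scores(c("Zeta", "Alpha", "Mid"), c(100, 100, 0)))
  expect_match(tied[[1]]$text, "^Alpha, Zeta recorded the highest")

  single <- interpret_ranking(fake_scores("Goa", 50))
  expect_length(single, 1)
  expect_match(single[[1]]$text, "both the top and bottom")

  expect_error(interpret_ranking(fake_scores(character(0), numeric(0))),
               class = "invalid_argument")
})

test_that("correlation wording reflects sign, strength bands, and significance", {
  s <- interpret_correlation(fake_corr(-0.446, 0.01))
  expect_match(s$text, "significant moderate negative association")
  expect_match(s$text, "r = -0.45, p = 0.01", fixed = TRUE)

  weak <- interpret_correlation(fake_corr(0.01, 0.90))
  expect_match(weak$text, "non-significant weak positive")

  zero <- interpret_correlation(fake_corr(0, 1))
  expect_match(zero$text, "no association")
  expect_no_match(zero$text, "positive|negative")

  strong <- interpret_correlation(fake_corr(0.8, 0.001))
  expect_match(strong$text, "significant strong positive")
})

test_that("test wording uses strict alpha and the sign of the mean difference", {
  ns <- interpret_test(fake_test(0.23), label = "PHC 24x7 availability")
  expect_equal(ns$text,
               "PHC 24x7 availability showed no statistically significant change (p = 0.23).")

  sig <- interpret_test(fake_test(0.04, mean_diff = 2.5), label = "Coverage")
  expect_match(sig$text, "statistically significant increase")

  boundary <- interpret_test(fake_test(0.05), label = "X")
  expect_match(boundary$text, "no statistically significant change")
})

test_that("cluster tiers are ordered by mean score with alphabetical members", {
  scores <- fake_scores(c("A", "B", "C", "D", "E", "F"),
                        c(95, 90, 50, 45, 5, 0))
  cl <- structure(list(labels = c(2L, 2L, 0L, 0L, 1L, 1L), k = 3L, seed = 42L,
                       unit_names = scores$unit_names, wcss = 0,
                       centroids = matrix(0, 3, 1)),
                  class = "cluster_result")
  tiers <- interpret_clusters(cl, scores)
  expect_length(tiers, 3)
  expect_match(tiers[[1]]$text, "high performance tier comprises 2 unit\\(s\\): A, B")
  expect_match(tiers[[2]]$text, "middle performance tier comprises 2 unit\\(s\\): C, D")
  expect_match(tiers[[3]]$text, "low performance tier comprises 2 unit\\(s\\): E, F")

  k1 <- structure(list(labels = rep(0L, 6), k = 1L, seed = 1L,
                       unit_names = scores$unit_names, wcss = 0,
                       centroids = matrix(0, 1, 1)),
                  class = "cluster_result")
  one <- interpret_clusters(k1, scores)
  expect_length(one, 1)
  expect_match(one[[1]]$text, "comprises 6 unit\\(s\\)")

  mismatched <- structure(list(labels = 0L, k = 1L, seed = 1L,
                               unit_names = "Z", wcss = 0,
                               centroids = matrix(0, 1, 1)),
                          class = "cluster_result")
  expect_error(interpret_clusters(mismatched, scores), class = "invalid_argument")
})

test_that("significance wording always agrees with p < alpha over random results", {
  cfg <- rule_config(alpha = 0.05)
  set.seed(77)
  for (i in 1:50) {
    p <- stats::runif(1)
    r <- stats::runif(1, -1, 1)
    s <- interpret_correlation(fake_corr(r, p), cfg)
    expect_equal(grepl("a significant", s$text, fixed = TRUE), p < cfg$alpha)
    ts <- interpret_test(fake_test(p, mean_diff = r), cfg, "L")
    expect_equal(grepl("no statistically significant", ts$text), !(p < cfg$alpha))
  }
})

test_that("templates fail loudly on unresolved placeholders", {
  cfg <- rule_config(templates = c(test_null = "{label} and {mystery} (p = {p})."))
  expect_error(interpret_test(fake_test(0.5), cfg, "X"), class = "template_error")
})

test_that("narratives are pure functions of the bundle, in fixed section order", {
  bundle <- demo_bundle()
  n1 <- build_narrative(bundle)
  n2 <- build_narrative(bundle)
  expect_identical(vapply(n1, `[[`, "", "text"), vapply(n2, `[[`, "", "text"))

  ids <- vapply(n1, `[[`, "", "rule_id")
  expect_equal(ids[1:2], c("ranking_top", "ranking_bottom"))
  expect_equal(ids[3:5], rep("cluster_tier", 3))
  expect_true(all(ids[6:20] %in% c("correlation", "correlation_null")))
  expect_true(ids[21] %in% c("test_significant", "test_null"))

  # omitting correlations omits the correlation section
  trimmed <- bundle
  trimmed$correlations <- list()
  ids2 <- vapply(build_narrative(trimmed), `[[`, "", "rule_id")
  expect_false(any(ids2 %in% c("correlation", "correlation_null")))
})

test_that("the demonstration narrative matches its frozen golden file", {
  texts <- vapply(build_narrative(demo_bundle()), `[[`, "", "text")
  golden <- readLines(test_path("golden_narrative.txt"))
  expect_identical(texts, golden)
})
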