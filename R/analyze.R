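# Analysis stage: z-score normalisation, unweighted composite scoring with
# 0-100 rescale and ranking, Pearson correlation, Welch and paired t-tests.

#' Column-wise z-score normalisation
#'
#' Standardises each indicator with its column mean and population standard
#' deviation (divisor n), putting heterogeneous scales on a common footing.
#' A constant column standardises to all zeros, with a warning.
#'
#' @param m Numeric matrix, units x indicators (>= 2 rows).
#' @return Matrix of the same shape.
#' @export
zscore <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) hp_stop("invalid_argument", "z-scoring needs at least 2 units")
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(sweep(m, 2, mu)^2))
  if (any(sigma == 0)) {
    hp_warn("constant column(s) %s standardised to zeros",
            paste(colnames(m)[sigma == 0] %||% which(sigma == 0), collapse = ", "))
    sigma[sigma == 0] <- 1
  }
  sweep(sweep(m, 2, mu), 2, sigma, "/")
}

#' Composite health score: unweighted mean of polarity-adjusted z-values
#'
#' The composite for each unit is the unweighted mean across indicators of
#' `polarity * z`, where polarity is +1 for "higher is better" indicators and
#' -1 otherwise. Composites are then rescaled linearly so the best unit scores
#' exactly 100 and the worst exactly 0. Ranks use competition ("min") ranking
#' with 1 = best; a degenerate all-equal composite maps every unit to 50.
#'
#' @param z Standardised matrix from [zscore()] with unit names as rownames.
#' @param polarity Numeric vector in \{+1, -1\}, one per indicator (recycled
#'   from length 1).
#' @return A `score_table`: `unit_names`, `z_matrix`, `composite_raw`,
#'   `score`, `rank`.
#' @export
composite_scores <- function(z, polarity = 1) {
  z <- as.matrix(z)
  if (length(polarity) == 1L) polarity <- rep(polarity, ncol(z))
  if (length(polarity) != ncol(z))
    hp_stop("invalid_argument", "polarity length %d != indicator count %d",
            length(polarity), ncol(z))
  if (!all(polarity %in% c(-1, 1)))
    hp_stop("invalid_argument", "polarity entries must be +1 or -1")
  composite <- rowMeans(sweep(z, 2, polarity, "*"))
  rng <- range(composite)
  if (rng[1] == rng[2]) {
    hp_warn("constant composite: all scores set to 50.0")
    score <- rep(50, length(composite))
  } else {
    score <- 100 * (composite - rng[1]) / (rng[2] - rng[1])
  }
  structure(
    list(unit_names = rownames(z) %||% as.character(seq_len(nrow(z))),
         z_matrix = z, composite_raw = composite, score = score,
         rank = rank(-score, ties.method = "min")),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d units, %d indicators\n",
              length(x$unit_names), ncol(x$z_matrix)))
  ord <- order(x$rank, x$unit_names)
  top <- utils::head(ord, 3L)
  cat("top:", paste(sprintf("%s (%.1f)", x$unit_names[top], x$score[top]),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Convert a score table to a data frame sorted by rank
#' @param x A `score_table`.
#' @param row.names,optional,... Unused; S3 compatibility.
#' @return Data frame with `unit`, `score`, `rank`.
#' @export
as.data.frame.score_table <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- data.frame(unit = x$unit_names, score = x$score, rank = x$rank,
                   stringsAsFactors = FALSE)
  df[order(df$rank, df$unit), , drop = FALSE]
}

#' Pearson correlation with two-sided significance
#'
#' Product-moment correlation with a two-sided p-value from the t distribution
#' with n - 2 degrees of freedom. A perfect correlation (|r| = 1) reports the
#' smallest representable positive p rather than zero.
#'
#' @param x,y Numeric vectors (paired complete cases, n >= 3, non-constant).
#' @param var_x,var_y Optional variable labels carried into the result.
#' @return A `correlation_result`: `var_x`, `var_y`, `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y, var_x = "x", var_y = "y") {
  if (length(x) != length(y)) hp_stop("invalid_argument", "x and y lengths differ")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) hp_stop("invalid_argument", "correlation needs n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    hp_stop("degenerate_correlation", "correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  p <- ct$p.value
  if (abs(ct$estimate) >= 1 || p == 0) p <- .Machine$double.xmin
  structure(list(var_x = var_x, var_y = var_y,
                 r = unname(ct$estimate), p = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s ~ %s: r = %.3f, p = %.3g, n = %d\n",
              x$var_x, x$var_y, x$r, x$p, x$n))
  invisible(x)
}

#' All-pairs correlation of selected indicators
#'
#' One [pearson_correlation()] per unordered pair of columns, in column order.
#' No multiple-comparison adjustment is applied; results are exploratory.
#' Degenerate pairs (constant columns) are skipped with a log entry.
#'
#' @param clean A `clean_table`.
#' @param columns Indicator names (>= 2); default all indicators.
#' @return List of `correlation_result`.
#' @export
correlation_matrix <- function(clean, columns = names(clean$indicators)) {
  columns <- intersect(columns, names(clean$indicators))
  if (length(columns) < 2L)
    hp_stop("invalid_argument", "correlation needs at least 2 indicator columns")
  out <- list()
  for (i in seq_along(columns)[-length(columns)]) {
    for (j in seq((i + 1L), length(columns))) {
      res <- tryCatch(
        pearson_correlation(clean$indicators[[columns[i]]],
                            clean$indicators[[columns[j]]],
                            var_x = columns[i], var_y = columns[j]),
        healthpipe_error = function(e) {
          hp_log("WARN", "analyze", "skipping degenerate pair %s ~ %s: %s",
                 columns[i], columns[j], conditionMessage(e))
          NULL
        })
      if (!is.null(res)) out[[length(out) + 1L]] <- res
    }
  }
  out
}

new_test_result <- function(kind, statistic, df, p, n1, n2, mean_diff) {
  structure(list(kind = kind, statistic = statistic, df = df, p = p,
                 n1 = n1, n2 = n2, mean_diff = mean_diff),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s t-test> t = %.3f, df = %.3f, p = %.3g (n1 = %d, n2 = %d)\n",
              sub("_", " ", x$kind), x$statistic, x$df, x$p, x$n1, x$n2))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Two-sided t-test not assuming equal variances, with Welch-Satterthwaite
#' degrees of freedom. Sample variances use divisor n - 1.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @return A `test_result` with `mean_diff = mean(a) - mean(b)`.
#' @export
welch_ttest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    hp_stop("invalid_argument", "each group needs >= 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(new_test_result("welch_two_sample", 0, length(a) + length(b) - 2, 1,
                             length(a), length(b), 0))
    hp_stop("degenerate_variance", "both groups have zero variance with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  new_test_result("welch_two_sample", unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, length(a), length(b), mean(a) - mean(b))
}

#' Paired t-test on post - pre differences
#'
#' Two-sided paired t-test: `t = mean(d) / (sd(d) / sqrt(n))` on differences
#' `d = post - pre`, df = n - 1. All-zero differences give t = 0, p = 1; a
#' constant nonzero difference is reported as an infinite statistic with the
#' smallest representable positive p.
#'
#' @param pre_vals,post_vals Numeric vectors of equal length n >= 2.
#' @return A `test_result` with `mean_diff = mean(post - pre)`.
#' @export
paired_ttest <- function(pre_vals, post_vals) {
  if (length(pre_vals) != length(post_vals))
    hp_stop("invalid_argument", "paired test needs equal-length vectors")
  ok <- stats::complete.cases(pre_vals, post_vals)
  d <- post_vals[ok] - pre_vals[ok]
  n <- length(d)
  if (n < 2L) hp_stop("invalid_argument", "paired test needs n >= 2 complete pairs")
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(new_test_result("paired", 0, n - 1, 1, n, n, 0))
    return(new_test_result("paired", sign(mean(d)) * Inf, n - 1,
                           .Machine$double.xmin, n, n, mean(d)))
  }
  tt <- stats::t.test(d, alternative = "two.sided")
  new_test_result("paired", unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, n, n, mean(d))
}

#' Run the configured analysis stage
#'
#' Builds the polarity-adjusted composite score table, clusters units on the
#' standardised indicator profile, computes the all-pairs correlations, and
#' runs any configured t-tests, returning everything as one bundle.
#'
#' @param clean A `clean_table`.
#' @param score_indicators Indicators entering the composite (default: all).
#' @param polarity Named numeric vector (+1/-1) per indicator; unnamed
#'   indicators default to +1.
#' @param cluster_indicators Indicators used for clustering (default: the
#'   score indicators).
#' @param k Number of clusters.
#' @param seed RNG seed for clustering.
#' @param n_restarts Independent k-means restarts.
#' @param correlation_columns Columns for [correlation_matrix()] (default: the
#'   score indicators).
#' @param tests List of test specs: `list(kind = "welch_two_sample"|"paired",
#'   column_a =, column_b =, label =)`.
#' @return An `analysis_bundle` with `scores`, `clusters`, `correlations`,
#'   `tests`.
#' @export
analyze_table <- function(clean,
                          score_indicators = names(clean$indicators),
                          polarity = NULL,
                          cluster_indicators = score_indicators,
                          k = 3L, seed = 42L, n_restarts = 10L,
                          correlation_columns = score_indicators,
                          tests = list()) {
  score_indicators <- intersect(score_indicators, names(clean$indicators))
  if (length(score_indicators) == 0L)
    hp_stop("config_error", "no score indicators present in the clean table")
  m <- do.call(cbind, clean$indicators[score_indicators])
  rownames(m) <- clean$unit_names
  pol <- rep(1, length(score_indicators))
  names(pol) <- score_indicators
  if (!is.null(polarity)) pol[intersect(names(polarity), score_indicators)] <-
    polarity[intersect(names(polarity), score_indicators)]
  z <- zscore(m)
  scores <- composite_scores(z, pol)

  cluster_indicators <- intersect(cluster_indicators, score_indicators)
  zc <- sweep(z[, cluster_indicators, drop = FALSE], 2,
              pol[cluster_indicators], "*")
  clusters <- kmeans_cluster(zc, k = k, seed = seed, n_restarts = n_restarts)

  correlations <- if (length(intersect(correlation_columns,
                                       names(clean$indicators))) >= 2L)
    correlation_matrix(clean, correlation_columns) else list()

  test_results <- lapply(tests, function(spec) {
    a <- clean$indicators[[spec$column_a]]
    b <- clean$indicators[[spec$column_b]]
    if (is.null(a) || is.null(b))
      hp_stop("config_error", "test references missing column '%s'",
              if (is.null(a)) spec$column_a else spec$column_b)
    res <- if (identical(spec$kind, "paired")) paired_ttest(a, b)
           else welch_ttest(a, b)
    res$label <- spec$label %||% paste(spec$column_a, "vs", spec$column_b)
    res
  })

  structure(list(scores = scores, clusters = clusters,
                 correlations = correlations, tests = test_results,
                 clean = clean),
            class = "analysis_bundle")
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat(sprintf("<analysis_bundle> %d units | k = %d clusters | %d correlation pair(s) | %d test(s)\n",
              length(x$scores$unit_names), x$clusters$k,
              length(x$correlations), length(x$tests)))
  invisible(x)
}
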