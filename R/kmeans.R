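# K-means stratification: Lloyd's algorithm with k-means++ seeding, multiple
# restarts, and deterministic behaviour under a fixed seed. Implemented
# directly so that seeding, restart policy and empty-cluster repair are
# explicit and reproducible; stats::kmeans is used as a cross-check in tests.

wcss_of <- function(points, centroids, labels) {
  sum((points - centroids[labels, , drop = FALSE])^2)
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance from the nearest chosen centre.
kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  centres <- integer(k)
  centres[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(points, 2, points[centres[1L], ], "-")^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) centres[j + 1L] <- sample.int(n, 1L)
    else centres[j + 1L] <- sample.int(n, 1L, prob = d2)
    d2 <- pmin(d2, rowSums(sweep(points, 2, points[centres[j + 1L], ], "-")^2))
  }
  points[centres, , drop = FALSE]
}

assign_labels <- function(points, centroids) {
  d <- outer(rowSums(points^2), rep(1, nrow(centroids))) -
    2 * points %*% t(centroids) +
    outer(rep(1, nrow(points)), rowSums(centroids^2))
  max.col(-d, ties.method = "first")
}

lloyd_once <- function(points, k, max_iter, tol) {
  centroids <- kmeanspp_init(points, k)
  labels <- assign_labels(points, centroids)
  for (iter in seq_len(max_iter)) {
    new_centroids <- centroids
    for (j in seq_len(k)) {
      members <- labels == j
      if (any(members)) {
        new_centroids[j, ] <- colMeans(points[members, , drop = FALSE])
      } else {
        # empty cluster: seize the point farthest from its current centroid
        d2 <- rowSums((points - centroids[labels, , drop = FALSE])^2)
        far <- which.max(d2)
        new_centroids[j, ] <- points[far, ]
        labels[far] <- j
      }
    }
    shift <- max(sqrt(rowSums((new_centroids - centroids)^2)))
    centroids <- new_centroids
    labels <- assign_labels(points, centroids)
    if (shift < tol) break
  }
  # final means so wcss is consistent with the reported labels
  for (j in seq_len(k)) {
    members <- labels == j
    if (any(members)) centroids[j, ] <- colMeans(points[members, , drop = FALSE])
  }
  list(labels = labels, centroids = centroids,
       wcss = wcss_of(points, centroids, labels))
}

#' K-means clustering with k-means++ seeding and restarts
#'
#' Lloyd's algorithm under squared Euclidean distance. `n_restarts`
#' independent k-means++ seedings are run from the given seed and the solution
#' with the lowest within-cluster sum of squares (WCSS) is kept. An empty
#' cluster is repaired by moving in the point farthest from its centroid.
#' Deterministic given `(points, k, seed)`.
#'
#' @param points Numeric matrix, n x d, no missing values.
#' @param k Number of clusters, 1 <= k <= n.
#' @param seed Integer RNG seed.
#' @param n_restarts Independent restarts (best WCSS kept).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Convergence threshold on the maximum centroid shift.
#' @return A `cluster_result`: `labels` (0-based, length n), `centroids`
#'   (k x d), `wcss`, `k`, `seed`.
#' @export
kmeans_cluster <- function(points, k = 3L, seed = 42L, n_restarts = 10L,
                           max_iter = 300L, tol = 1e-6) {
  points <- as.matrix(points)
  if (anyNA(points)) hp_stop("invalid_argument", "points contain missing values")
  if (!is_count(k) || k > nrow(points))
    hp_stop("invalid_argument", "need n >= k >= 1 (n = %d, k = %s)", nrow(points), k)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_once(points, k, max_iter, tol)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  structure(list(labels = best$labels - 1L, centroids = best$centroids,
                 wcss = best$wcss, k = as.integer(k), seed = as.integer(seed),
                 unit_names = rownames(points)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, n = %d, wcss = %.4f (seed %d)\n",
              x$k, length(x$labels), x$wcss, x$seed))
  cat("sizes:", paste(tabulate(x$labels + 1L, x$k), collapse = ", "), "\n")
  invisible(x)
}
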