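# Shared fixtures and independent oracles.

no_sleep <- function(s) invisible(NULL)

# Fast api_config for tests: no real waiting ever happens because fetch_*
# receive sleep_fn = no_sleep.
test_api_config <- function(...) api_config(page_size = 10L, ...)

demo_spec <- function(...) {
  args <- utils::modifyList(list(aggregate_rows = c("India", "All India"),
                                 seed = 42L), list(...))
  do.call(synthetic_spec, args)
}

packaged_fixture_path <- function() {
  system.file("extdata", "synthetic_health_indicators.csv", package = "healthpipe")
}

demo_clean <- function() {
  raw <- with(parse_csv_payload(paste0(
    paste(readLines(packaged_fixture_path()), collapse = "\n"), "\n")),
    raw_table(header, rows))
  preprocess_table(raw)
}

demo_bundle <- function() {
  clean <- demo_clean()
  analyze_table(clean, tests = list(list(
    kind = "paired", column_a = "phc_24x7_dlhs_3", column_b = "phc_24x7_dlhs_4",
    label = "PHC 24x7 availability, DLHS-3 to DLHS-4")))
}

# A transport that fails a scripted number of times before delegating to a
# mock API, recording every call.
flaky_transport <- function(api, fail_first_k, status = 503L) {
  flaky <- mock_api(serve_all_csv(api), fail_first_k = fail_first_k,
                    fail_status = status)
  mock_transport(flaky)
}

serve_all_csv <- function(api) {
  serve_pages(api, 0L, max(1L, length(api$rows)))$body
}

serialize_clean <- function(clean) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(as.data.frame(clean), con, row.names = FALSE)
  close(con)
  paste(out, collapse = "\n")
}

# --- independent oracles ---

# Product-moment correlation from first principles (population moments).
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2) / n); sy <- sqrt(sum((y - my)^2) / n)
  r <- sum((x - mx) * (y - my)) / (n * sx * sy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

zscore_oracle <- function(m) {
  apply(m, 2, function(col) (col - mean(col)) / sqrt(mean((col - mean(col))^2)))
}

# Global k-means optimum by exhaustive enumeration of all assignments of n
# points to k non-empty groups (feasible for n <= 9, k <= 3).
kmeans_exhaustive_oracle <- function(points, k) {
  n <- nrow(points)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    labels <- grid[i, ]
    if (length(unique(labels)) < k) next
    wcss <- 0
    for (g in seq_len(k)) {
      pts <- points[labels == g, , drop = FALSE]
      ctr <- colMeans(pts)
      wcss <- wcss + sum(sweep(pts, 2, ctr)^2)
    }
    if (wcss < best) best <- wcss
  }
  best
}

three_blobs <- function(seed = 7L, n_per = 5L, sd = 0.05) {
  centers <- matrix(c(0, 0, 10, 0, 0, 10), ncol = 2, byrow = TRUE)
  set.seed(seed)
  pts <- do.call(rbind, lapply(1:3, function(i)
    cbind(stats::rnorm(n_per, centers[i, 1], sd),
          stats::rnorm(n_per, centers[i, 2], sd))))
  list(points = pts, truth = rep(1:3, each = n_per))
}

docx_document_xml <- function(path) {
  exdir <- tempfile("docx_unzip_")
  utils::unzip(path, exdir = exdir)
  xml2::read_xml(file.path(exdir, "word", "document.xml"))
}
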