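# Synthetic data: state-level indicator tables with realistic mess (string
# numbers, sporadic missingness, national summary rows, dirty headers) and an
# in-process mock API so ingestion is testable with no network.

INDIA_UNITS <- c(
  "Andhra Pradesh", "Arunachal Pradesh", "Assam", "Bihar", "Chhattisgarh",
  "Goa", "Gujarat", "Haryana", "Himachal Pradesh", "Jammu & Kashmir",
  "Jharkhand", "Karnataka", "Kerala", "Madhya Pradesh", "Maharashtra",
  "Manipur", "Meghalaya", "Mizoram", "Nagaland", "Odisha", "Punjab",
  "Rajasthan", "Sikkim", "Tamil Nadu", "Telangana", "Tripura",
  "Uttar Pradesh", "Uttarakhand", "West Bengal",
  "Andaman & Nicobar Islands", "Chandigarh", "Dadra & Nagar Haveli",
  "Daman & Diu", "Delhi", "Lakshadweep", "Puducherry", "Other Territories"
)

#' Default indicator specifications for the synthetic generator
#'
#' Six state-level indicators on heterogeneous scales: facility counts
#' (sub-health centres, primary health centres), staffing counts (auxiliary
#' nurse midwives, specialist doctors) and round-the-clock PHC service
#' coverage in two consecutive national facility-survey rounds.
#'
#' @return List of `list(name, mean, sd, kind)` specs.
#' @export
default_indicator_specs <- function() {
  list(
    list(name = "SHC Functioning",        mean = 10000, sd = 4000, kind = "count"),
    list(name = "PHC 24x7 DLHS-3 (%)",    mean = 50,    sd = 18,   kind = "percent"),
    list(name = "PHC 24x7 DLHS-4 (%)",    mean = 55,    sd = 18,   kind = "percent"),
    list(name = "ANM at SHC",             mean = 12000, sd = 5000, kind = "count"),
    list(name = "Specialist Doctors",     mean = 600,   sd = 300,  kind = "count"),
    list(name = "PHC Functioning",        mean = 1500,  sd = 600,  kind = "count")
  )
}

# Default dependence structure: facility-count indicators co-move (states with
# more sub-centres also run more PHCs), the two survey rounds of 24x7 PHC
# coverage track each other, and 24x7 coverage trades off mildly against ANM
# staffing.
default_correlation <- function() {
  cm <- diag(6)
  cm[1, 6] <- cm[6, 1] <- 0.5   # SHC ~ PHC functioning
  cm[2, 3] <- cm[3, 2] <- 0.7   # DLHS-3 ~ DLHS-4 coverage
  cm[3, 4] <- cm[4, 3] <- -0.3  # 24x7 coverage ~ ANM staffing
  cm
}

#' Specification for a synthetic indicator table
#'
#' Describes the study conditions the generator emulates: ~37 named
#' administrative units, a handful of numeric indicators on heterogeneous
#' scales with a configurable correlation structure, sporadic missingness,
#' formatted ("1,234") numbers, aggregate summary rows, and messy headers.
#'
#' @param n_units Number of unit rows (default 37).
#' @param unit_name_pool Names to draw units from, in order.
#' @param indicator_specs List of `list(name, mean, sd, kind)` where `kind` is
#'   `"count"` (rounded, floored at 0) or `"percent"` (clamped to 0-100).
#' @param correlation d x d positive-semidefinite matrix with unit diagonal.
#' @param missing_rate Probability a unit-level cell is blanked (MCAR).
#' @param aggregate_rows Labels of summary rows appended after the unit rows;
#'   their indicator cells hold column sums over the unit rows.
#' @param messy_headers Dirty the header (mixed case, stray spaces, symbols)?
#' @param string_numbers Format large numbers with thousands separators?
#' @param seed Integer seed; the generated CSV is byte-identical per seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_units = 37L,
                           unit_name_pool = INDIA_UNITS,
                           indicator_specs = default_indicator_specs(),
                           correlation = NULL,
                           missing_rate = 0.05,
                           aggregate_rows = c("India"),
                           messy_headers = TRUE,
                           string_numbers = TRUE,
                           seed = 42L) {
  d <- length(indicator_specs)
  if (is.null(correlation))
    correlation <- if (d == 6L) default_correlation() else diag(d)
  if (!isSymmetric(unname(correlation)) || any(abs(diag(correlation) - 1) > 1e-12))
    hp_stop("spec_error", "correlation must be symmetric with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    hp_stop("spec_error", "correlation matrix is not positive semi-definite")
  if (missing_rate < 0 || missing_rate >= 1)
    hp_stop("spec_error", "missing_rate must lie in [0, 1)")
  if (n_units > length(unit_name_pool))
    hp_stop("spec_error", "n_units exceeds the unit name pool (%d > %d)",
            n_units, length(unit_name_pool))
  structure(list(n_units = as.integer(n_units), unit_name_pool = unit_name_pool,
                 indicator_specs = indicator_specs, correlation = correlation,
                 missing_rate = missing_rate, aggregate_rows = aggregate_rows,
                 messy_headers = messy_headers, string_numbers = string_numbers,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

csv_field <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

format_thousands <- function(x) formatC(x, format = "d", big.mark = ",")

#' Generate a synthetic indicator table as CSV text
#'
#' Draws unit rows from a multivariate normal with the spec's means, standard
#' deviations and correlation, then applies the indicated realism: counts are
#' rounded and floored at zero, percentages clamped to 0-100, cells blanked
#' completely at random at `missing_rate`, large counts formatted with
#' thousands separators, and summary rows (column sums) appended. Seeded and
#' byte-reproducible.
#'
#' @param spec A [synthetic_spec()].
#' @return A single CSV string (header + rows, LF line endings).
#' @export
generate_table <- function(spec) {
  d <- length(spec$indicator_specs)
  mu <- vapply(spec$indicator_specs, `[[`, 1, "mean")
  sd <- vapply(spec$indicator_specs, `[[`, 1, "sd")
  kind <- vapply(spec$indicator_specs, function(s) s$kind %||% "count", "")
  sigma <- diag(sd) %*% spec$correlation %*% diag(sd)
  with_seed(spec$seed, {
    x <- MASS::mvrnorm(spec$n_units, mu = mu, Sigma = sigma)
    x[, kind == "count"] <- pmax(round(x[, kind == "count", drop = FALSE]), 0)
    x[, kind == "percent"] <- round(pmin(pmax(x[, kind == "percent", drop = FALSE], 0), 100), 1)
    miss <- matrix(stats::runif(spec$n_units * d) < spec$missing_rate,
                   spec$n_units, d)
  })
  units <- spec$unit_name_pool[seq_len(spec$n_units)]

  header <- c("State/UT", vapply(spec$indicator_specs, `[[`, "", "name"))
  if (!spec$messy_headers)
    header <- c("state_ut", harmonize_columns(vapply(spec$indicator_specs, `[[`, "", "name")))

  fmt_cell <- function(value, k) {
    if (k == "count" && spec$string_numbers && value >= 1000) format_thousands(value)
    else format(value, scientific = FALSE, trim = TRUE)
  }
  lines <- vapply(seq_len(spec$n_units), function(i) {
    cells <- vapply(seq_len(d), function(j) {
      if (miss[i, j]) "" else fmt_cell(x[i, j], kind[j])
    }, "")
    paste(csv_field(c(units[i], cells)), collapse = ",")
  }, "")

  agg_lines <- vapply(spec$aggregate_rows, function(label) {
    sums <- vapply(seq_len(d), function(j) {
      s <- sum(x[!miss[, j], j])
      if (kind[j] == "percent") fmt_cell(round(s, 1), "percent")
      else fmt_cell(round(s), "count")
    }, "")
    paste(csv_field(c(label, sums)), collapse = ",")
  }, "")

  paste0(paste(c(paste(csv_field(header), collapse = ","), lines, agg_lines),
               collapse = "\n"), "\n")
}

#' In-process mock of a paginated, optionally flaky CSV API
#'
#' Serves slices of a fixture CSV through the same transport contract the
#' ingestion stage uses for live endpoints. The first `fail_first_k` requests
#' return `fail_status`, emulating an unstable server; all later requests
#' succeed.
#'
#' @param csv_text Fixture CSV (e.g. from [generate_table()]).
#' @param fail_first_k Number of initial requests that fail.
#' @param fail_status HTTP status for scripted failures (default 503).
#' @return A `mock_api` (mutable: counts requests across calls).
#' @export
mock_api <- function(csv_text, fail_first_k = 0L, fail_status = 503L) {
  parsed <- parse_csv_payload(csv_text)
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  structure(list(header = parsed$header, rows = parsed$rows,
                 fail_first_k = as.integer(fail_first_k),
                 fail_status = as.integer(fail_status), state = env),
            class = "mock_api")
}

#' Serve one page from a mock API
#'
#' @param api A [mock_api()].
#' @param offset Row offset (>= 0).
#' @param limit Page size (>= 1).
#' @return List with `status_code` and `body` (CSV with header; zero data rows
#'   past the end of the fixture).
#' @export
serve_pages <- function(api, offset, limit) {
  if (offset < 0 || limit < 1) hp_stop("invalid_argument", "need offset >= 0, limit >= 1")
  api$state$calls <- api$state$calls + 1L
  if (api$state$calls <= api$fail_first_k)
    return(list(status_code = api$fail_status, body = "service unavailable"))
  n <- length(api$rows)
  idx <- seq.int(offset + 1L, length.out = min(limit, max(0L, n - offset)))
  if (offset >= n) idx <- integer(0)
  body_rows <- vapply(api$rows[idx], function(r) paste(csv_field(r), collapse = ","), "")
  list(status_code = 200L,
       body = paste0(paste(c(paste(csv_field(api$header), collapse = ","), body_rows),
                           collapse = "\n"), "\n"))
}

#' Transport adapter over a mock API
#'
#' @param api A [mock_api()].
#' @return A transport function `(url, query, timeout)` honouring the
#'   `offset`/`limit` query parameters, for use with [fetch_all()].
#' @export
mock_transport <- function(api) {
  function(url, query, timeout) {
    offset <- as.integer(query[["offset"]] %||% 0L)
    limit <- as.integer(query[["limit"]] %||% length(api$rows))
    serve_pages(api, offset, limit)
  }
}

#' Write a synthetic fixture CSV (and its spec) to disk
#'
#' @param dir Output directory (created if needed).
#' @param spec A [synthetic_spec()].
#' @param name Base filename (without extension).
#' @return Invisible list with `csv` and `spec` paths.
#' @export
write_fixture <- function(dir, spec = synthetic_spec(), name = "synthetic_indicators") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(dir, paste0(name, ".csv"))
  writeLines(sub("\n$", "", generate_table(spec)), csv_path)
  spec_path <- file.path(dir, paste0(name, "_spec.json"))
  jsonlite::write_json(
    list(n_units = spec$n_units, missing_rate = spec$missing_rate,
         aggregate_rows = spec$aggregate_rows, seed = spec$seed,
         indicators = lapply(spec$indicator_specs, function(s)
           list(name = s$name, mean = s$mean, sd = s$sd))),
    spec_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(csv = csv_path, spec = spec_path))
}
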