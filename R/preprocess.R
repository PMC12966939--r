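# Preprocessing stage: harmonise headers, coerce numerics, drop aggregate
# rows, impute medians, derive features; keep a row-count audit trail.

DEFAULT_AGGREGATE_LABELS <- c("india", "all india", "total")
DEFAULT_MISSING_TOKENS <- c("", "NA", "N/A", "-", "–", "..")
DEFAULT_UNIT_CANDIDATES <- c("state", "state_ut", "states_uts", "unit", "state_uts")

#' Harmonise raw column names
#'
#' Lower-cases, trims, collapses runs of non-alphanumeric characters to single
#' underscores, and strips leading/trailing underscores. Name collisions are
#' resolved by suffixing `_2`, `_3`, ... The transformation is idempotent.
#'
#' @param header Character vector of raw column names.
#' @return Character vector of canonical names, same length.
#' @export
harmonize_columns <- function(header) {
  if (length(header) == 0L) hp_stop("invalid_argument", "header must be non-empty")
  canon <- tolower(trimws(header))
  canon <- gsub("[^a-z0-9]+", "_", canon)
  canon <- gsub("^_+|_+$", "", canon)
  if (any(!nzchar(canon)))
    hp_stop("naming_error", "column %d ('%s') harmonises to an empty name",
            which(!nzchar(canon))[1L], header[which(!nzchar(canon))[1L]])
  out <- canon
  for (i in seq_along(canon)) {
    if (sum(canon[seq_len(i)] == canon[i]) > 1L)
      out[i] <- paste0(canon[i], "_", sum(canon[seq_len(i)] == canon[i]))
  }
  out
}

#' Coerce string cells to numeric values
#'
#' Strips thousands separators (commas) and surrounding whitespace; parses
#' `%`-suffixed values as the bare number; maps tokens in `missing_tokens` to
#' `NA`. Unparseable non-missing tokens become `NA` with a warning. Total
#' function: never errors.
#'
#' @param cells Character vector.
#' @param missing_tokens Tokens treated as missing (matched after trimming).
#' @param quiet Suppress the unparseable-token warning (used when probing
#'   columns that may turn out to be non-numeric).
#' @return List with `values` (numeric, `NA` for missing) and `n_unparseable`.
#' @export
coerce_numeric <- function(cells, missing_tokens = DEFAULT_MISSING_TOKENS,
                           quiet = FALSE) {
  x <- trimws(as.character(cells))
  missing <- x %in% missing_tokens | is.na(cells)
  y <- gsub(",", "", x)
  y <- sub("%$", "", trimws(y))
  vals <- suppressWarnings(as.numeric(y))
  unparseable <- !missing & is.na(vals)
  if (any(unparseable) && !quiet)
    hp_warn("%d unparseable token(s) treated as missing (e.g. '%s')",
            sum(unparseable), x[which(unparseable)[1L]])
  vals[missing] <- NA_real_
  list(values = vals, n_unparseable = sum(unparseable))
}

#' Remove aggregate/summary rows
#'
#' Drops rows whose trimmed, case-folded unit name is in `aggregate_labels`
#' (default: "india", "all india", "total"), preserving the order of surviving
#' rows. National summary rows would otherwise dominate unit-level statistics.
#'
#' @param df Data frame of units.
#' @param unit_column Name of the unit-name column.
#' @param aggregate_labels Labels (case-insensitive) identifying summary rows.
#' @return List with `data` (surviving rows) and `dropped_labels` (original
#'   unit names of removed rows, in order of appearance).
#' @export
drop_aggregate_rows <- function(df, unit_column,
                                aggregate_labels = DEFAULT_AGGREGATE_LABELS) {
  if (!unit_column %in% names(df))
    hp_stop("invalid_argument", "unit column '%s' not found", unit_column)
  key <- tolower(trimws(df[[unit_column]]))
  drop <- key %in% tolower(trimws(aggregate_labels))
  list(data = df[!drop, , drop = FALSE],
       dropped_labels = df[[unit_column]][drop])
}

#' Median imputation of one indicator column
#'
#' Replaces missing entries with the median of the observed entries (even
#' counts: mean of the two central values). Observed values are never changed.
#'
#' @param column Numeric vector, possibly with `NA`.
#' @return List with `values` (complete numeric vector) and `n_imputed`.
#' @export
impute_median <- function(column) {
  obs <- column[!is.na(column)]
  if (length(obs) == 0L)
    hp_stop("all_missing_column", "column has no observed values; drop it upstream")
  m <- stats::median(obs)
  n_imp <- sum(is.na(column))
  column[is.na(column)] <- m
  list(values = column, n_imputed = n_imp)
}

#' Region map for feature derivation
#'
#' @param mapping Named character vector: unit name -> region label. Lookup is
#'   case-insensitive on trimmed names.
#' @param default_label Label for unmapped units.
#' @return A `region_map`.
#' @export
region_map <- function(mapping = character(0), default_label = "unclassified") {
  names(mapping) <- tolower(trimws(names(mapping)))
  structure(list(mapping = mapping, default_label = default_label),
            class = "region_map")
}

#' Read a region map from a two-column CSV (unit,region)
#' @param path CSV file path.
#' @param default_label Label for unmapped units.
#' @return A [region_map()].
#' @export
read_region_map <- function(path, default_label = "unclassified") {
  df <- utils::read.csv(path, colClasses = "character")
  region_map(stats::setNames(df[[2L]], df[[1L]]), default_label)
}

#' Derive engineered features
#'
#' Adds a `region` categorical column from a [region_map()] and, optionally,
#' arithmetic indicators defined in config as a ratio (`numerator`/
#' `denominator`) or difference (`minuend` - `subtrahend`) of existing columns.
#' Division by zero yields a missing value (with a warning) which is then
#' median-imputed like any other gap.
#'
#' @param clean A `clean_table`.
#' @param regions A [region_map()], or `NULL` to skip the region column.
#' @param derived_indicators List of specs, each
#'   `list(name=, numerator=, denominator=)` or `list(name=, minuend=, subtrahend=)`.
#' @return The augmented `clean_table`.
#' @export
derive_features <- function(clean, regions = NULL, derived_indicators = list()) {
  if (!is.null(regions)) {
    key <- tolower(trimws(clean$unit_names))
    lab <- unname(regions$mapping[key])
    lab[is.na(lab)] <- regions$default_label
    clean$derived$region <- lab
  }
  for (spec in derived_indicators) {
    refs <- unlist(spec[setdiff(names(spec), "name")], use.names = FALSE)
    missing_cols <- setdiff(refs, names(clean$indicators))
    if (length(missing_cols))
      hp_stop("config_error", "derived indicator '%s' references missing column '%s'",
              spec$name, missing_cols[1L])
    if (!is.null(spec$numerator)) {
      den <- clean$indicators[[spec$denominator]]
      v <- clean$indicators[[spec$numerator]] / den
      if (any(den == 0)) {
        hp_warn("derived indicator '%s': division by zero in %d row(s), imputing",
                spec$name, sum(den == 0))
        v[den == 0] <- NA_real_
      }
    } else {
      v <- clean$indicators[[spec$minuend]] - clean$indicators[[spec$subtrahend]]
    }
    imp <- if (anyNA(v)) impute_median(v) else list(values = v, n_imputed = 0L)
    clean$indicators[[spec$name]] <- imp$values
    clean$audit$imputed_cell_count <- clean$audit$imputed_cell_count + imp$n_imputed
  }
  clean
}

new_clean_table <- function(unit_names, indicators, derived, audit) {
  stopifnot(all(vapply(indicators, length, 1L) == length(unit_names)))
  structure(list(unit_names = unit_names, indicators = indicators,
                 derived = derived, audit = audit),
            class = "clean_table")
}

#' @export
print.clean_table <- function(x, ...) {
  cat(sprintf("<clean_table> %d units x %d indicators\n",
              length(x$unit_names), length(x$indicators)))
  cat("indicators:", paste(names(x$indicators), collapse = ", "), "\n")
  a <- x$audit
  cat(sprintf("audit: %d rows in, %d after aggregate removal, %d cells imputed\n",
              a$rows_in, a$rows_after_aggregate_removal, a$imputed_cell_count))
  invisible(x)
}

#' Convert a clean table to a data frame
#' @param x A `clean_table`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A data frame with `unit`, derived columns, then indicators.
#' @export
as.data.frame.clean_table <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- data.frame(unit = x$unit_names, stringsAsFactors = FALSE)
  if (length(x$derived))
    out <- cbind(out, as.data.frame(x$derived, stringsAsFactors = FALSE,
                                    optional = TRUE))
  cbind(out, as.data.frame(x$indicators, optional = TRUE))
}

resolve_unit_column <- function(names_canon, candidates, numeric_share) {
  hit <- intersect(candidates, names_canon)
  if (length(hit)) return(match(hit[1L], names_canon))
  nonnum <- which(numeric_share < 0.5)
  if (length(nonnum)) return(nonnum[1L])
  NA_integer_
}

#' Preprocess a raw table into a typed clean table
#'
#' Applies, in order: column harmonisation, numeric coercion, aggregate-row
#' removal, dropping of all-missing columns, median imputation per indicator,
#' and feature derivation. The returned audit records row counts before and
#' after aggregate removal, imputed-cell counts, and dropped columns, so every
#' run is verifiable. Deterministic: identical input yields identical output.
#'
#' @param raw A [raw_table()].
#' @param unit_column_candidates Canonical names tried for the unit column;
#'   if none matches, the first mostly non-numeric column is used.
#' @param aggregate_labels Passed to [drop_aggregate_rows()].
#' @param missing_tokens Passed to [coerce_numeric()].
#' @param regions Optional [region_map()].
#' @param derived_indicators Passed to [derive_features()].
#' @return A `clean_table`.
#' @export
preprocess_table <- function(raw,
                             unit_column_candidates = DEFAULT_UNIT_CANDIDATES,
                             aggregate_labels = DEFAULT_AGGREGATE_LABELS,
                             missing_tokens = DEFAULT_MISSING_TOKENS,
                             regions = NULL,
                             derived_indicators = list()) {
  if (length(raw$rows) == 0L) hp_stop("preprocess_error", "raw table has no rows")
  canon <- harmonize_columns(raw$header)
  df <- as.data.frame(do.call(rbind, raw$rows), stringsAsFactors = FALSE)
  names(df) <- canon

  coerced <- lapply(df, coerce_numeric, missing_tokens = missing_tokens,
                    quiet = TRUE)
  numeric_share <- vapply(coerced, function(cc) mean(!is.na(cc$values)), 1)
  unit_idx <- resolve_unit_column(canon, unit_column_candidates, numeric_share)
  if (is.na(unit_idx))
    hp_stop("preprocess_error", "no unit column resolvable (tried: %s)",
            paste(unit_column_candidates, collapse = ", "))
  unit_col <- canon[unit_idx]
  hp_log("INFO", "preprocess", "unit column: '%s'", unit_col)
  for (col in setdiff(canon, unit_col))
    if (coerced[[col]]$n_unparseable > 0L)
      hp_warn("column '%s': %d unparseable token(s) treated as missing",
              col, coerced[[col]]$n_unparseable)

  rows_in <- nrow(df)
  drop_mask <- tolower(trimws(df[[unit_col]])) %in% tolower(trimws(aggregate_labels))
  dropped <- list(dropped_labels = df[[unit_col]][drop_mask])
  keep <- which(!drop_mask)
  df <- df[keep, , drop = FALSE]

  unit_names <- trimws(df[[unit_col]])
  if (anyDuplicated(unit_names))
    hp_stop("preprocess_error", "duplicate unit name '%s' after aggregate removal",
            unit_names[anyDuplicated(unit_names)])

  indicator_cols <- setdiff(canon, unit_col)
  indicators <- list()
  dropped_cols <- character(0)
  n_imputed <- 0L
  for (col in indicator_cols) {
    vals <- coerced[[col]]$values[keep]
    if (all(is.na(vals))) {
      dropped_cols <- c(dropped_cols, col)
      hp_log("INFO", "preprocess", "dropping all-missing column '%s'", col)
      next
    }
    imp <- impute_median(vals)
    indicators[[col]] <- imp$values
    n_imputed <- n_imputed + imp$n_imputed
  }
  if (length(indicators) == 0L)
    hp_stop("preprocess_error", "every indicator column is all-missing")

  audit <- structure(list(
    rows_in = rows_in,
    rows_after_aggregate_removal = nrow(df),
    dropped_aggregate_labels = dropped$dropped_labels,
    imputed_cell_count = n_imputed,
    dropped_all_missing_columns = dropped_cols
  ), class = "row_audit")
  hp_log("INFO", "preprocess",
         "%d rows in, %d after aggregate removal, %d cells imputed, %d columns dropped",
         rows_in, nrow(df), n_imputed, length(dropped_cols))

  clean <- new_clean_table(unit_names, indicators, list(), audit)
  derive_features(clean, regions = regions, derived_indicators = derived_indicators)
}
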