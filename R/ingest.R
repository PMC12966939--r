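# Ingestion stage: paginated retrieval of CSV payloads from a REST endpoint,
# with exponential-backoff retry and fetch provenance.

#' API endpoint configuration
#'
#' Describes a paginated CSV-serving REST endpoint in the style of national
#' open-data portals: a base URL plus a resource identifier, an API key, and
#' `offset`/`limit` pagination parameters with `format=csv`.
#'
#' @param base_url Endpoint base URL (ignored by in-process mock transports).
#' @param resource_id Opaque resource identifier appended to the URL path.
#' @param api_key Static API key; may be `NA` for mock transports.
#' @param page_size Rows requested per page (>= 1).
#' @param max_attempts Maximum attempts per page, including the first (>= 1).
#' @param backoff_base Base delay in seconds for the exponential backoff (> 0).
#' @param timeout Per-request timeout in seconds.
#' @param param_names Named list mapping the roles `offset`, `limit`, `format`
#'   and `api_key` to the query-parameter names the endpoint expects.
#' @return An `api_config` object.
#' @export
api_config <- function(base_url = "",
                       resource_id = "",
                       api_key = NA_character_,
                       page_size = 100L,
                       max_attempts = 5L,
                       backoff_base = 1,
                       timeout = 30,
                       param_names = list(offset = "offset", limit = "limit",
                                          format = "format", api_key = "api-key")) {
  if (!is_count(page_size)) hp_stop("invalid_argument", "page_size must be a positive integer")
  if (!is_count(max_attempts)) hp_stop("invalid_argument", "max_attempts must be a positive integer")
  if (!is.numeric(backoff_base) || backoff_base <= 0)
    hp_stop("invalid_argument", "backoff_base must be > 0")
  structure(
    list(base_url = base_url, resource_id = resource_id, api_key = api_key,
         page_size = as.integer(page_size), max_attempts = as.integer(max_attempts),
         backoff_base = backoff_base, timeout = timeout, param_names = param_names),
    class = "api_config"
  )
}

#' Exponential backoff delay schedule
#'
#' Delay before retry number `attempt`, following the geometric schedule
#' `base * 2^(attempt - 1)`: 1 s, 2 s, 4 s, ... for the default base of one
#' second. No jitter is applied, keeping retry timing deterministic.
#'
#' @param attempt Attempt number (1 = first retry), positive integer.
#' @param base Base delay in seconds.
#' @return Delay in seconds.
#' @export
backoff_delay <- function(attempt, base = 1) {
  if (!is_count(attempt)) hp_stop("invalid_argument", "attempt must be a positive integer")
  base * 2^(attempt - 1)
}

#' Parse one CSV payload into header and string rows
#'
#' Parses RFC-4180-style CSV text (quoted fields may contain commas and
#' newlines) into an untyped header + rows-of-strings pair. All typing is
#' deferred to the preprocessing stage.
#'
#' @param body CSV text.
#' @return List with `header` (character) and `rows` (list of character vectors).
#' @export
parse_csv_payload <- function(body) {
  if (!is_string(body) || !nzchar(trimws(body)))
    hp_stop("parse_error", "empty CSV payload")
  nfields <- utils::count.fields(textConnection(body), sep = ",", quote = "\"",
                                 blank.lines.skip = TRUE)
  if (length(unique(nfields)) > 1L) {
    bad <- which(nfields != nfields[1L])[1L]
    hp_stop("parse_error", "ragged CSV: row %d has %d fields, expected %d",
            bad - 1L, nfields[bad], nfields[1L])
  }
  df <- utils::read.csv(text = body, header = TRUE, colClasses = "character",
                        check.names = FALSE, strip.white = FALSE,
                        blank.lines.skip = TRUE)
  rows <- if (nrow(df) == 0L) list() else
    lapply(seq_len(nrow(df)), function(i) as.character(unlist(df[i, ], use.names = FALSE)))
  list(header = names(df), rows = rows)
}

new_fetch_provenance <- function(request_count, retry_count, per_page_row_counts,
                                 started_at, finished_at) {
  structure(
    list(request_count = request_count, retry_count = retry_count,
         per_page_row_counts = per_page_row_counts,
         started_at = started_at, finished_at = finished_at),
    class = "fetch_provenance"
  )
}

#' Construct a raw (untyped) table
#'
#' @param header Character vector of column names.
#' @param rows List of character vectors, each of length `length(header)`.
#' @param provenance Optional `fetch_provenance` record.
#' @return A `raw_table`.
#' @export
raw_table <- function(header, rows, provenance = NULL) {
  if (length(header) == 0L) hp_stop("invalid_argument", "header must be non-empty")
  bad <- which(vapply(rows, length, 1L) != length(header))
  if (length(bad))
    hp_stop("invalid_argument", "row %d has %d cells, expected %d",
            bad[1L], length(rows[[bad[1L]]]), length(header))
  structure(list(header = header, rows = rows, provenance = provenance),
            class = "raw_table")
}

#' @export
print.raw_table <- function(x, ...) {
  cat(sprintf("<raw_table> %d rows x %d columns\n", length(x$rows), length(x$header)))
  cat("columns:", paste(x$header, collapse = ", "), "\n")
  if (!is.null(x$provenance))
    cat(sprintf("fetched in %d request(s), %d retr%s\n",
                x$provenance$request_count, x$provenance$retry_count,
                if (x$provenance$retry_count == 1L) "y" else "ies"))
  invisible(x)
}

build_query <- function(config, offset) {
  pn <- config$param_names
  q <- list()
  q[[pn$format]] <- "csv"
  q[[pn$offset]] <- offset
  q[[pn$limit]] <- config$page_size
  if (!is.na(config$api_key) && nzchar(config$api_key)) q[[pn$api_key]] <- config$api_key
  q
}

retryable_status <- function(status) is.na(status) || status >= 500

#' Fetch one page of rows, retrying transient failures
#'
#' Issues a GET through `transport` for one page at the given row offset.
#' Connection errors, timeouts and HTTP 5xx responses are retried up to
#' `config$max_attempts` times with [backoff_delay()] between attempts; HTTP
#' 4xx responses are treated as configuration errors and never retried.
#'
#' @param config An [api_config()].
#' @param offset Row offset (>= 0).
#' @param transport Function `(url, query, timeout)` returning a list with
#'   `status_code` (NA for a connection-level failure) and `body` (CSV text).
#' @param sleep_fn Function used to sleep between attempts (injectable so tests
#'   run without waiting).
#' @return List with `rows` (list of character vectors), `header`, and
#'   `retries` (number of retries performed).
#' @export
fetch_page <- function(config, offset, transport, sleep_fn = Sys.sleep) {
  if (!is.numeric(offset) || offset < 0) hp_stop("invalid_argument", "offset must be >= 0")
  url <- paste0(config$base_url, config$resource_id)
  query <- build_query(config, offset)
  history <- character(0)
  for (attempt in seq_len(config$max_attempts)) {
    resp <- tryCatch(transport(url, query, config$timeout),
                     error = function(e) list(status_code = NA_integer_,
                                              body = conditionMessage(e)))
    status <- resp$status_code
    hp_log("INFO", "ingest", "GET offset=%s attempt=%d status=%s",
           offset, attempt, if (is.na(status)) "connection-error" else status)
    if (!is.na(status) && status >= 200 && status < 300) {
      parsed <- parse_csv_payload(resp$body)
      return(list(header = parsed$header, rows = parsed$rows, retries = attempt - 1L))
    }
    history <- c(history, sprintf("attempt %d: %s", attempt,
                                  if (is.na(status)) "connection error" else paste("HTTP", status)))
    if (!retryable_status(status)) {
      hp_stop("config_error",
              "non-retryable HTTP %d at offset %s (check API key / resource id)",
              status, offset, data = list(attempts = history))
    }
    if (attempt < config$max_attempts) sleep_fn(backoff_delay(attempt, config$backoff_base))
  }
  hp_stop("ingestion_failure", "page at offset %s failed after %d attempts",
          offset, config$max_attempts, data = list(attempts = history))
}

#' Retrieve all records from a paginated endpoint
#'
#' Walks offsets 0, page_size, 2*page_size, ... concatenating pages until a
#' page returns fewer than `page_size` rows (including zero). The header is
#' taken from the first page; a header mismatch on a later page aborts the
#' ingestion. Pagination is lossless and order-preserving.
#'
#' @inheritParams fetch_page
#' @return A [raw_table()] with fetch provenance attached.
#' @export
fetch_all <- function(config, transport, sleep_fn = Sys.sleep) {
  started <- Sys.time()
  header <- NULL
  rows <- list()
  per_page <- integer(0)
  retries <- 0L
  requests <- 0L
  offset <- 0L
  repeat {
    page <- fetch_page(config, offset, transport, sleep_fn = sleep_fn)
    requests <- requests + 1L + page$retries
    retries <- retries + page$retries
    if (is.null(header)) {
      header <- page$header
    } else if (!identical(header, page$header)) {
      hp_stop("ingestion_failure", "header mismatch at offset %s", offset)
    }
    per_page <- c(per_page, length(page$rows))
    rows <- c(rows, page$rows)
    if (length(page$rows) < config$page_size) break
    offset <- offset + config$page_size
  }
  prov <- new_fetch_provenance(requests, retries, per_page, started, Sys.time())
  hp_log("INFO", "ingest", "retrieved %d rows in %d request(s) (%d retries)",
         length(rows), requests, retries)
  raw_table(header, rows, prov)
}

#' Live HTTP transport
#'
#' A transport closure for real endpoints, backed by the curl package. Mock
#' transports from [mock_transport()] satisfy the same contract offline.
#'
#' @return A function `(url, query, timeout)` returning `list(status_code, body)`.
#' @export
http_transport <- function() {
  if (!requireNamespace("curl", quietly = TRUE))
    hp_stop("config_error", "the curl package is required for live HTTP ingestion")
  function(url, query, timeout) {
    qs <- paste(vapply(names(query), function(k)
      paste0(utils::URLencode(k, reserved = TRUE), "=",
             utils::URLencode(as.character(query[[k]]), reserved = TRUE)), ""),
      collapse = "&")
    h <- curl::new_handle(timeout = as.integer(timeout))
    res <- curl::curl_fetch_memory(paste0(url, "?", qs), handle = h)
    list(status_code = res$status_code, body = rawToChar(res$content))
  }
}
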