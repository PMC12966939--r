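test_that("backoff schedule doubles per attempt and rejects bad input", {
  expect_equal(backoff_delay(1, 1.0), 1.0)
  expect_equal(backoff_delay(3, 1.0), 4.0)
  expect_equal(backoff_delay(4, 0.5), 4.0)
  delays <- vapply(1:8, backoff_delay, 1, base = 0.25)
  expect_true(all(diff(delays) >= 0))
  expect_error(backoff_delay(0), class = "invalid_argument")
})

test_that("CSV payload parsing honours RFC-4180 quoting and flags raggedness", {
  out <- parse_csv_payload('a,b\n1,"x,y"')
  expect_equal(out$header, c("a", "b"))
  expect_equal(out$rows, list(c("1", "x,y")))

  empty <- parse_csv_payload("a,b\n")
  expect_equal(empty$header, c("a", "b"))
  expect_length(empty$rows, 0)

  err <- expect_error(parse_csv_payload("a,b\n1"), class = "parse_error")
  expect_match(conditionMessage(err), "row 1")
  expect_error(parse_csv_payload(""), class = "parse_error")
})

test_that("fetch_page retries transient failures and rejects 4xx immediately", {
  csv <- generate_table(demo_spec(n_units = 10L, aggregate_rows = character(0)))
  cfg <- test_api_config()

  ok <- fetch_page(cfg, 0L, mock_transport(mock_api(csv)), sleep_fn = no_sleep)
  expect_length(ok$rows, 10)
  expect_equal(ok$retries, 0L)

  flaky <- mock_transport(mock_api(csv, fail_first_k = 2L))
  recovered <- fetch_page(cfg, 0L, flaky, sleep_fn = no_sleep)
  expect_length(recovered$rows, 10)
  expect_equal(recovered$retries, 2L)

  dead <- mock_transport(mock_api(csv, fail_first_k = 99L))
  expect_error(fetch_page(cfg, 0L, dead, sleep_fn = no_sleep),
               class = "ingestion_failure")

  denied <- function(url, query, timeout) list(status_code = 403L, body = "no")
  expect_error(fetch_page(cfg, 0L, denied, sleep_fn = no_sleep),
               class = "config_error")
})

test_that("retry delays follow the geometric schedule and calls = 1 + retries", {
  csv <- generate_table(demo_spec(n_units = 5L, aggregate_rows = character(0)))
  calls <- 0L
  delays <- numeric(0)
  api <- mock_api(csv, fail_first_k = 3L)
  counting <- function(url, query, timeout) {
    calls <<- calls + 1L
    mock_transport(api)(url, query, timeout)
  }
  res <- fetch_page(api_config(page_size = 5L, backoff_base = 0.5), 0L, counting,
                    sleep_fn = function(s) delays <<- c(delays, s))
  expect_equal(calls, 4L)
  expect_equal(res$retries, 3L)
  expect_equal(delays, c(0.5, 1.0, 2.0))
})

test_that("pagination concatenates complete pages with provenance", {
  csv <- generate_table(demo_spec(aggregate_rows = character(0)))
  raw <- fetch_all(test_api_config(), mock_transport(mock_api(csv)),
                   sleep_fn = no_sleep)
  expect_length(raw$rows, 37)
  expect_equal(raw$provenance$per_page_row_counts, c(10L, 10L, 10L, 7L))
  expect_equal(raw$provenance$retry_count, 0L)
  expect_equal(sum(raw$provenance$per_page_row_counts), length(raw$rows))

  # total divisible by page size: an extra empty page terminates
  csv20 <- generate_table(demo_spec(n_units = 20L, aggregate_rows = character(0)))
  raw20 <- fetch_all(api_config(page_size = 20L), mock_transport(mock_api(csv20)),
                     sleep_fn = no_sleep)
  expect_length(raw20$rows, 20)
  expect_equal(raw20$provenance$per_page_row_counts, c(20L, 0L))

  empty <- fetch_all(test_api_config(), mock_transport(mock_api("a,b\n")),
                     sleep_fn = no_sleep)
  expect_length(empty$rows, 0)
  expect_equal(empty$provenance$request_count, 1L)
})

test_that("pagination is lossless and order-preserving for any page size", {
  csv <- generate_table(demo_spec(aggregate_rows = character(0)))
  reference <- parse_csv_payload(csv)
  for (p in c(1L, 5L, 10L, 37L, 50L)) {
    raw <- fetch_all(api_config(page_size = p), mock_transport(mock_api(csv)),
                     sleep_fn = no_sleep)
    expect_identical(raw$rows, reference$rows, label = sprintf("page_size %d", p))
    expect_identical(raw$header, reference$header)
  }
})

test_that("fetch_all is deterministic and detects header drift", {
  csv <- generate_table(demo_spec(aggregate_rows = character(0)))
  r1 <- fetch_all(test_api_config(), mock_transport(mock_api(csv)), sleep_fn = no_sleep)
  r2 <- fetch_all(test_api_config(), mock_transport(mock_api(csv)), sleep_fn = no_sleep)
  expect_identical(r1$rows, r2$rows)

  drifting <- function(url, query, timeout) {
    off <- as.integer(query[["offset"]])
    hdr <- if (off == 0) "a,b" else "a,c"
    list(status_code = 200L, body = paste0(hdr, "\n", paste(rep("1,2", 10), collapse = "\n"), "\n"))
  }
  expect_error(fetch_all(test_api_config(), drifting, sleep_fn = no_sleep),
               class = "ingestion_failure")
})
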