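test_that("column harmonisation canonicalises, resolves collisions, is idempotent", {
  expect_equal(harmonize_columns(c(" SHC  Functioning ", "PHC 24x7 (%)")),
               c("shc_functioning", "phc_24x7"))
  expect_equal(harmonize_columns(c("A", "a ")), c("a", "a_2"))
  expect_error(harmonize_columns("%"), class = "naming_error")

  headers <- list(c("State/UT", "No. of SHCs", "ANM @ SHC", "x", "X"),
                  c("a b", "a_b", "a-b"))
  for (h in headers) {
    once <- harmonize_columns(h)
    expect_identical(harmonize_columns(once), once)
  }
})

test_that("numeric coercion strips separators, percent signs, missing tokens", {
  out <- coerce_numeric(c("1,234", " 5 ", "NA"))
  expect_equal(out$values, c(1234, 5, NA))
  expect_equal(coerce_numeric("12%")$values, 12)
  expect_warning(bad <- coerce_numeric("abc"))
  expect_true(is.na(bad$values))
  expect_equal(bad$n_unparseable, 1L)
  expect_equal(coerce_numeric(c("", "-", "..", "N/A"))$values, rep(NA_real_, 4))
})

test_that("aggregate rows are removed case-insensitively, order preserved", {
  df <- data.frame(state = c("Kerala", "India", "Goa", "All India", "india "),
                   v = 1:5, stringsAsFactors = FALSE)
  out <- drop_aggregate_rows(df, "state")
  expect_equal(out$data$state, c("Kerala", "Goa"))
  expect_equal(out$dropped_labels, c("India", "All India", "india "))

  clean <- drop_aggregate_rows(data.frame(state = c("Goa", "Kerala"), v = 1:2), "state")
  expect_equal(nrow(clean$data), 2)
  expect_length(clean$dropped_labels, 0)
})

test_that("median imputation fills gaps without touching observed values", {
  expect_equal(impute_median(c(2, NA, 4)), list(values = c(2, 3, 4), n_imputed = 1L))
  expect_equal(impute_median(c(1, 2, 3))$n_imputed, 0L)
  expect_equal(impute_median(c(5, NA, NA, 9, 7))$values, c(5, 7, 7, 9, 7))
  expect_error(impute_median(c(NA_real_, NA_real_)), class = "all_missing_column")

  # observed values unchanged; median preserved
  set.seed(11)
  for (i in 1:20) {
    col <- stats::rnorm(15)
    col[sample(15, 4)] <- NA
    obs <- !is.na(col)
    imp <- impute_median(col)
    expect_identical(imp$values[obs], col[obs])
    expect_equal(stats::median(imp$values[obs]), stats::median(col[obs]))
  }
})

test_that("feature derivation maps regions and guards division by zero", {
  clean <- demo_clean()
  rm_path <- system.file("extdata", "india_region_map.csv", package = "healthpipe")
  with_regions <- derive_features(clean, read_region_map(rm_path, "unknown"))
  expect_equal(with_regions$derived$region[clean$unit_names == "Meghalaya"],
               "North-East")
  expect_equal(with_regions$derived$region[clean$unit_names == "Other Territories"],
               "unknown")

  none <- derive_features(clean, region_map(character(0), "unmapped"))
  expect_true(all(none$derived$region == "unmapped"))

  small <- list(unit_names = c("A", "B", "C"),
                indicators = list(a = c(2, 4, 6), b = c(1, 0, 2)),
                derived = list(),
                audit = list(imputed_cell_count = 0L))
  class(small) <- "clean_table"
  expect_warning(
    out <- derive_features(small, NULL,
                           list(list(name = "ratio", numerator = "a", denominator = "b"))),
    "division by zero")
  expect_equal(out$indicators$ratio, c(2, 2.5, 3))  # imputed with median of {2,3}
  expect_equal(out$audit$imputed_cell_count, 1L)
  expect_error(
    derive_features(small, NULL, list(list(name = "x", numerator = "a", denominator = "zz"))),
    class = "config_error")
})

test_that("full preprocessing of the packaged fixture leaves 37 complete records", {
  clean <- demo_clean()
  expect_length(clean$unit_names, 37)
  expect_equal(clean$audit$rows_in, 39)
  expect_equal(clean$audit$rows_after_aggregate_removal, 37)
  expect_setequal(clean$audit$dropped_aggregate_labels, c("India", "All India"))
  expect_false(anyNA(unlist(clean$indicators)))
  expect_false(anyDuplicated(clean$unit_names) > 0)
  # audit conservation
  expect_equal(clean$audit$rows_in - clean$audit$rows_after_aggregate_removal,
               length(clean$audit$dropped_aggregate_labels))
})

test_that("preprocessing is deterministic, tolerant of clean input, strict on empty", {
  clean1 <- demo_clean()
  clean2 <- demo_clean()
  expect_identical(serialize_clean(clean1), serialize_clean(clean2))

  tidy <- raw_table(c("state", "a", "b"),
                    list(c("X", "1", "2"), c("Y", "3", "4")))
  out <- preprocess_table(tidy)
  expect_equal(out$audit$imputed_cell_count, 0L)
  expect_length(out$audit$dropped_aggregate_labels, 0)
  expect_length(out$audit$dropped_all_missing_columns, 0)

  allmiss <- raw_table(c("state", "a"), list(c("X", "NA"), c("Y", "-")))
  expect_error(preprocess_table(allmiss), class = "preprocess_error")

  nounit <- raw_table(c("v1", "v2"), list(c("1", "2"), c("3", "4")))
  expect_error(preprocess_table(nounit), class = "preprocess_error")
})

test_that("an all-missing column is dropped and audited rather than fatal", {
  raw <- raw_table(c("state", "good", "empty"),
                   list(c("X", "1", "NA"), c("Y", "2", "-"), c("Z", "3", "")))
  clean <- preprocess_table(raw)
  expect_equal(names(clean$indicators), "good")
  expect_equal(clean$audit$dropped_all_missing_columns, "empty")
})
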