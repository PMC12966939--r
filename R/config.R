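# Pipeline configuration: YAML/JSON schema validation with exhaustive error
# reporting, default filling, and rejection of unknown keys.

config_schema <- function() {
  list(
    input = list(
      fixture_path = list(type = "character", default = NULL),
      api = list(
        base_url = list(type = "character", default = ""),
        resource_id = list(type = "character", default = ""),
        api_key = list(type = "character", default = NA_character_),
        page_size = list(type = "count", default = 100L),
        max_attempts = list(type = "count", default = 5L),
        backoff_base = list(type = "positive", default = 1),
        timeout = list(type = "positive", default = 30),
        param_names = list(type = "list",
                           default = list(offset = "offset", limit = "limit",
                                          format = "format", api_key = "api-key"))
      )
    ),
    preprocess = list(
      unit_column_candidates = list(type = "character_vec",
                                    default = DEFAULT_UNIT_CANDIDATES),
      aggregate_labels = list(type = "character_vec",
                              default = DEFAULT_AGGREGATE_LABELS),
      missing_tokens = list(type = "character_vec",
                            default = DEFAULT_MISSING_TOKENS),
      region_map_path = list(type = "character", default = NULL),
      region_default_label = list(type = "character", default = "unclassified"),
      derived_indicators = list(type = "list", default = list())
    ),
    analyze = list(
      score_indicators = list(type = "character_vec", default = NULL),
      polarity = list(type = "list", default = list()),
      cluster_indicators = list(type = "character_vec", default = NULL),
      k = list(type = "count", default = 3L),
      seed = list(type = "count", default = 42L),
      n_restarts = list(type = "count", default = 10L),
      correlation_columns = list(type = "character_vec", default = NULL),
      tests = list(type = "list", default = list())
    ),
    interpret = list(
      alpha = list(type = "unit_interval", default = 0.05),
      r_bands = list(type = "numeric_vec", default = c(0.3, 0.5)),
      templates_path = list(type = "character", default = NULL)
    ),
    report = list(
      output_dir = list(type = "character", default = "."),
      prefix = list(type = "character", default = "report"),
      title = list(type = "character", default = "Public Health Indicator Report")
    ),
    log_level = list(type = "character", default = "INFO")
  )
}

check_leaf <- function(value, type, path, errors) {
  bad <- switch(type,
    character = !is_string(value) && !is.na(value),
    character_vec = !is.character(value) || length(value) == 0L,
    numeric_vec = !is.numeric(value),
    count = !is_count(value),
    positive = !(is.numeric(value) && length(value) == 1L && value > 0),
    unit_interval = !(is.numeric(value) && length(value) == 1L &&
                        value > 0 && value < 1),
    list = !is.list(value),
    FALSE)
  if (isTRUE(bad)) c(errors, sprintf("%s: expected %s", path, type)) else errors
}

walk_schema <- function(schema, raw, path, errors) {
  out <- list()
  is_leaf <- function(node) !is.null(node$type)
  unknown <- setdiff(names(raw), names(schema))
  for (u in unknown)
    errors <- c(errors, sprintf("unknown key: %s", paste(c(path, u), collapse = ".")))
  for (key in names(schema)) {
    node <- schema[[key]]
    here <- paste(c(path, key), collapse = ".")
    if (is_leaf(node)) {
      if (is.null(raw[[key]])) {
        out[[key]] <- node$default
      } else {
        val <- raw[[key]]
        if (node$type == "character_vec") val <- as.character(unlist(val))
        if (node$type == "numeric_vec") val <- as.numeric(unlist(val))
        errors <- check_leaf(val, node$type, here, errors)
        out[[key]] <- val
      }
    } else {
      sub <- walk_schema(node, raw[[key]] %||% list(), c(path, key), errors)
      out[[key]] <- sub$config
      errors <- sub$errors
    }
  }
  list(config = out, errors = errors)
}

#' Validate a pipeline configuration
#'
#' Parses YAML or JSON, type-checks every key against the schema, fills
#' defaults, and rejects unknown keys. All schema violations are reported
#' together, not first-failure-only. Exactly one input mode must be set:
#' `input.fixture_path` (offline CSV) or `input.api.base_url` (live endpoint).
#'
#' @param source Path to a YAML/JSON file, or a raw config list.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(source) {
  raw <- if (is.character(source)) {
    if (!file.exists(source)) hp_stop("config_error", "config file %s not found", source)
    if (grepl("\\.json$", source)) jsonlite::read_json(source, simplifyVector = FALSE)
    else yaml::read_yaml(source)
  } else if (is.list(source)) source else
    hp_stop("config_error", "config must be a file path or a list")
  res <- walk_schema(config_schema(), raw %||% list(), character(0), character(0))
  cfg <- res$config
  errors <- res$errors

  has_fixture <- !is.null(cfg$input$fixture_path)
  has_api <- nzchar(cfg$input$api$base_url %||% "")
  if (has_fixture && has_api)
    errors <- c(errors, "input: set either input.fixture_path or input.api.base_url, not both")
  if (!has_fixture && !has_api)
    errors <- c(errors, "input: one of input.fixture_path or input.api.base_url is required")
  if (has_fixture && !file.exists(cfg$input$fixture_path))
    errors <- c(errors, sprintf("input.fixture_path: file %s not found", cfg$input$fixture_path))
  if (!is.null(cfg$preprocess$region_map_path) &&
      !file.exists(cfg$preprocess$region_map_path))
    errors <- c(errors, sprintf("preprocess.region_map_path: file %s not found",
                                cfg$preprocess$region_map_path))
  if (!is.null(cfg$interpret$templates_path) &&
      !file.exists(cfg$interpret$templates_path))
    errors <- c(errors, sprintf("interpret.templates_path: file %s not found",
                                cfg$interpret$templates_path))
  if (length(cfg$interpret$r_bands) != 2L || diff(cfg$interpret$r_bands) <= 0)
    errors <- c(errors, "interpret.r_bands: expected two increasing thresholds")
  if (!cfg$log_level %in% c("DEBUG", "INFO", "WARN", "ERROR"))
    errors <- c(errors, "log_level: must be one of DEBUG, INFO, WARN, ERROR")

  if (length(errors))
    hp_stop("config_error", "invalid configuration:\n  - %s",
            paste(errors, collapse = "\n  - "), data = list(errors = errors))
  cfg$mode <- if (has_fixture) "fixture" else "api"
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> mode = %s | k = %d, seed = %d | alpha = %.2f\n",
              x$mode, x$analyze$k, x$analyze$seed, x$interpret$alpha))
  invisible(x)
}
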