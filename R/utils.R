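#' @keywords internal
#' @importFrom ggplot2 .data
"_PACKAGE"

# Internal helpers shared across stages.

`%||%` <- function(x, y) if (is.null(x)) y else x

hp_stop <- function(class, msg, ..., data = list()) {
  cond <- structure(
    class = c(class, "healthpipe_error", "error", "condition"),
    c(list(message = sprintf(msg, ...), call = sys.call(-1)), data)
  )
  stop(cond)
}

hp_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

hp_log <- function(level, stage, msg, ...) {
  levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)
  threshold <- getOption("healthpipe.log_level", "INFO")
  if (levels[[level]] < levels[[threshold]]) return(invisible(NULL))
  message(sprintf("[%s] %s: %s", level, stage, sprintf(msg, ...)))
  invisible(NULL)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so pipeline stages do not perturb user randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

fmt_num <- function(x, digits = 2L) formatC(x, format = "f", digits = digits)
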