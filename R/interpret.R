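# Interpretation stage: deterministic conditional-logic rules that turn
# analytical outputs into narrative sentences, each carrying its rule id and
# the evidence values interpolated into the template.

default_templates <- function() {
  c(
    ranking_top = "{units} recorded the highest composite score ({score}).",
    ranking_bottom = "{units} recorded the lowest composite score ({score}).",
    ranking_single = "{units} is both the top and bottom performer ({score}).",
    cluster_tier = "The {tier} comprises {n} unit(s): {units}.",
    correlation = "There is a {significance} {strength}{direction} association between {var_x} and {var_y} (r = {r}, p = {p}).",
    correlation_null = "There is no association between {var_x} and {var_y} (r = {r}, p = {p}).",
    test_significant = "{label} showed a statistically significant {direction} (p = {p}).",
    test_null = "{label} showed no statistically significant change (p = {p})."
  )
}

#' Interpretation rule configuration
#'
#' @param alpha Significance threshold (strict: significant iff p < alpha).
#' @param r_bands Two increasing thresholds on |r| separating weak / moderate /
#'   strong associations; defaults 0.3 and 0.5.
#' @param templates Named character vector of sentence templates with
#'   `{placeholder}` slots, overriding the defaults per rule id.
#' @return A `rule_config`.
#' @export
rule_config <- function(alpha = 0.05, r_bands = c(0.3, 0.5), templates = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    hp_stop("invalid_argument", "alpha must lie in (0, 1)")
  if (length(r_bands) != 2L || diff(r_bands) <= 0 || any(r_bands <= 0 | r_bands >= 1))
    hp_stop("invalid_argument", "r_bands must be two increasing values in (0, 1)")
  tpl <- default_templates()
  if (!is.null(templates)) tpl[names(templates)] <- templates
  structure(list(alpha = alpha, r_bands = r_bands, templates = tpl),
            class = "rule_config")
}

#' Load narrative templates from a YAML file keyed by rule id
#' @param path YAML file path.
#' @param ... Passed to [rule_config()].
#' @return A `rule_config` with the file's templates merged over the defaults.
#' @export
read_rule_config <- function(path, ...) {
  tpl <- unlist(yaml::read_yaml(path))
  rule_config(templates = tpl, ...)
}

# Fill {placeholder} slots; an unresolved placeholder is a hard error so a
# template/evidence mismatch can never reach a report silently.
render_template <- function(template, evidence) {
  out <- template
  for (key in names(evidence))
    out <- gsub(paste0("{", key, "}"), as.character(evidence[[key]]), out,
                fixed = TRUE)
  left <- regmatches(out, gregexpr("\\{[a-z_0-9]+\\}", out))[[1]]
  if (length(left))
    hp_stop("template_error", "unresolved placeholder(s): %s",
            paste(left, collapse = ", "))
  out
}

new_statement <- function(rule_id, template, evidence) {
  structure(list(rule_id = rule_id,
                 text = render_template(template, evidence),
                 evidence = evidence),
            class = "narrative_statement")
}

#' @export
print.narrative_statement <- function(x, ...) {
  cat(sprintf("[%s] %s\n", x$rule_id, x$text))
  invisible(x)
}

#' Name the top- and bottom-performing units
#'
#' Emits one statement for the rank-1 unit(s) and one for the bottom unit(s);
#' tied units are listed alphabetically. Scores are printed to one decimal,
#' matching the composite scale's report style.
#'
#' @param scores A `score_table`.
#' @param cfg A [rule_config()].
#' @return List of two `narrative_statement`s.
#' @export
interpret_ranking <- function(scores, cfg = rule_config()) {
  if (length(scores$unit_names) == 0L) hp_stop("invalid_argument", "empty score table")
  top <- sort(scores$unit_names[scores$score == max(scores$score)])
  bottom <- sort(scores$unit_names[scores$score == min(scores$score)])
  if (length(scores$unit_names) == 1L)
    return(list(new_statement("ranking_single", cfg$templates[["ranking_single"]],
                              list(units = top,
                                   score = fmt_num(max(scores$score), 1L)))))
  list(
    new_statement("ranking_top", cfg$templates[["ranking_top"]],
                  list(units = paste(top, collapse = ", "),
                       score = fmt_num(max(scores$score), 1L))),
    new_statement("ranking_bottom", cfg$templates[["ranking_bottom"]],
                  list(units = paste(bottom, collapse = ", "),
                       score = fmt_num(min(scores$score), 1L)))
  )
}

#' Describe a correlation result in words
#'
#' Direction from the sign of r, strength from |r| against the configured
#' bands, significance from p < alpha (strict). An exactly zero r is reported
#' as "no association" with neither direction word.
#'
#' @param c A `correlation_result`.
#' @param cfg A [rule_config()].
#' @return A `narrative_statement`.
#' @export
interpret_correlation <- function(c, cfg = rule_config()) {
  ev <- list(var_x = c$var_x, var_y = c$var_y,
             r = fmt_num(c$r), p = fmt_num(c$p))
  if (c$r == 0)
    return(new_statement("correlation_null", cfg$templates[["correlation_null"]], ev))
  ev$direction <- if (c$r > 0) "positive" else "negative"
  ev$strength <- if (abs(c$r) < cfg$r_bands[1]) "weak "
                 else if (abs(c$r) < cfg$r_bands[2]) "moderate "
                 else "strong "
  ev$significance <- if (c$p < cfg$alpha) "significant" else "non-significant"
  new_statement("correlation", cfg$templates[["correlation"]], ev)
}

#' Describe a t-test result in words
#'
#' "Statistically significant" iff p < alpha (strict); when significant, the
#' direction of change comes from the sign of the mean difference. P-values
#' are reported to two decimals.
#'
#' @param t A `test_result`.
#' @param cfg A [rule_config()].
#' @param label Human-readable label for the comparison.
#' @return A `narrative_statement`.
#' @export
interpret_test <- function(t, cfg = rule_config(), label = "The comparison") {
  ev <- list(label = label, p = fmt_num(t$p))
  if (t$p < cfg$alpha) {
    ev$direction <- if (t$mean_diff > 0) "increase"
                    else if (t$mean_diff < 0) "decrease" else "difference"
    new_statement("test_significant", cfg$templates[["test_significant"]], ev)
  } else {
    new_statement("test_null", cfg$templates[["test_null"]], ev)
  }
}

#' Label clusters as performance tiers
#'
#' Orders clusters by descending mean composite score and labels them
#' "high/middle/low performance tier" for k = 3 (generic "performance tier
#' 1..k" otherwise), emitting one statement per tier with its members listed
#' alphabetically. Ties on mean score break by smallest member name.
#'
#' @param cl A `cluster_result`.
#' @param scores A `score_table` over the same units.
#' @param cfg A [rule_config()].
#' @return List of `narrative_statement`s, highest tier first.
#' @export
interpret_clusters <- function(cl, scores, cfg = rule_config()) {
  if (!setequal(cl$unit_names %||% scores$unit_names, scores$unit_names) ||
      length(cl$labels) != length(scores$unit_names))
    hp_stop("invalid_argument", "cluster and score tables cover different units")
  idx <- if (is.null(cl$unit_names)) seq_along(scores$unit_names)
         else match(cl$unit_names, scores$unit_names)
  means <- vapply(seq_len(cl$k) - 1L, function(g)
    mean(scores$score[idx[cl$labels == g]]), 1)
  first_member <- vapply(seq_len(cl$k) - 1L, function(g)
    min(scores$unit_names[idx[cl$labels == g]]), "")
  ord <- order(-means, first_member)
  tier_names <- if (cl$k == 3L) c("high performance tier", "middle performance tier",
                                  "low performance tier")
                else paste("performance tier", seq_len(cl$k))
  lapply(seq_along(ord), function(pos) {
    g <- ord[pos] - 1L
    members <- sort(scores$unit_names[idx[cl$labels == g]])
    new_statement("cluster_tier", cfg$templates[["cluster_tier"]],
                  list(tier = tier_names[pos], n = length(members),
                       units = paste(members, collapse = ", ")))
  })
}

#' Build the full narrative for one analysis bundle
#'
#' A pure function of (bundle, cfg): sections are emitted in the fixed order
#' ranking, clusters, correlations, tests, so identical bundles always yield
#' byte-identical narratives.
#'
#' @param bundle An `analysis_bundle` from [analyze_table()].
#' @param cfg A [rule_config()].
#' @return Ordered list of `narrative_statement`s.
#' @export
build_narrative <- function(bundle, cfg = rule_config()) {
  out <- interpret_ranking(bundle$scores, cfg)
  out <- c(out, interpret_clusters(bundle$clusters, bundle$scores, cfg))
  for (cr in bundle$correlations) out <- c(out, list(interpret_correlation(cr, cfg)))
  for (tt in bundle$tests)
    out <- c(out, list(interpret_test(tt, cfg, label = tt$label %||% "The comparison")))
  out
}

#' Export narrative evidence as JSON for audit
#' @param statements List of `narrative_statement`s.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_narrative_audit <- function(statements, path) {
  payload <- lapply(statements, function(s)
    list(rule_id = s$rule_id, text = s$text, evidence = s$evidence))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
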