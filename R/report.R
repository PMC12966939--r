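# Reporting stage: assemble the Word document from the analysis bundle and
# narrative, under a collision-safe timestamped filename. Tables are derived
# from the serialised analysis outputs; nothing is recomputed here.

#' Collision-safe timestamped output path
#'
#' `outdir/prefix_YYYYMMDD_HHMMSS.docx`; when that file already exists (two
#' runs within one second), `_2`, `_3`, ... is appended. Path separators in
#' the prefix are sanitised to underscores.
#'
#' @param outdir Existing output directory.
#' @param prefix Filename prefix.
#' @param now Timestamp (`POSIXct`); defaults to the current time.
#' @param ext File extension.
#' @return A path that does not yet exist.
#' @export
timestamped_path <- function(outdir, prefix, now = Sys.time(), ext = ".docx") {
  if (!dir.exists(outdir)) hp_stop("io_error", "output directory %s does not exist", outdir)
  prefix <- gsub("[/\\\\]+", "_", prefix)
  stamp <- format(now, "%Y%m%d_%H%M%S")
  path <- file.path(outdir, paste0(prefix, "_", stamp, ext))
  i <- 1L
  while (file.exists(path)) {
    i <- i + 1L
    path <- file.path(outdir, paste0(prefix, "_", stamp, "_", i, ext))
  }
  path
}

ranking_table <- function(scores) {
  df <- as.data.frame(scores)
  data.frame(Unit = df$unit, Score = fmt_num(df$score, 1L), Rank = df$rank,
             stringsAsFactors = FALSE)
}

cluster_table <- function(clusters, scores) {
  units <- clusters$unit_names %||% scores$unit_names
  df <- data.frame(Unit = units, Cluster = clusters$labels,
                   stringsAsFactors = FALSE)
  df[order(df$Cluster, df$Unit), , drop = FALSE]
}

correlation_table <- function(correlations) {
  do.call(rbind, lapply(correlations, function(cc)
    data.frame(Pair = paste(cc$var_x, "~", cc$var_y),
               r = fmt_num(cc$r, 3L), p = fmt_num(cc$p, 3L), n = cc$n,
               stringsAsFactors = FALSE)))
}

test_table <- function(tests) {
  do.call(rbind, lapply(tests, function(tt)
    data.frame(Comparison = tt$label %||% tt$kind, Kind = tt$kind,
               t = fmt_num(tt$statistic, 3L), df = fmt_num(tt$df, 2L),
               p = fmt_num(tt$p, 3L), stringsAsFactors = FALSE)))
}

#' Build the Word report for one pipeline run
#'
#' Writes a .docx containing the title, a methods summary, the ranking,
#' cluster-membership and correlation tables, the narrative paragraphs, and
#' the embedded figures with captions. No manual post-editing is required.
#'
#' @param bundle An `analysis_bundle`.
#' @param narrative List of `narrative_statement`s from [build_narrative()].
#' @param figures Figure artifacts from [render_figures()] (possibly empty).
#' @param outdir Output directory (created if needed).
#' @param title Report title.
#' @param prefix Filename prefix for [timestamped_path()].
#' @param now Timestamp used for the filename and the header line.
#' @return Path of the written .docx.
#' @export
build_docx <- function(bundle, narrative, figures = list(),
                       outdir = ".", title = "Public Health Indicator Report",
                       prefix = "report", now = Sys.time()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  missing_figs <- vapply(figures, function(f) !file.exists(f$path), TRUE)
  if (any(missing_figs))
    hp_stop("io_error", "figure file missing: %s", figures[[which(missing_figs)[1]]]$path)
  path <- timestamped_path(outdir, prefix, now)

  doc <- docx_document()
  docx_add_heading(doc, title, 1L)
  docx_add_paragraph(doc, paste("Generated:", format(now, "%Y-%m-%d %H:%M:%S")))

  docx_add_heading(doc, "Methods summary", 2L)
  docx_add_paragraph(doc, paste(
    "Indicators were z-score normalised and aggregated as an unweighted mean",
    "into a composite score rescaled to 0-100. Units were stratified with",
    sprintf("k-means clustering (k = %d, fixed seed %d).", bundle$clusters$k,
            bundle$clusters$seed),
    "Pearson correlations and t-tests are exploratory; no multiple-comparison",
    "adjustment was applied."))

  docx_add_heading(doc, "Key findings", 2L)
  if (length(narrative) == 0L) {
    docx_add_paragraph(doc, "No findings were generated for this run.")
  } else {
    for (s in narrative) docx_add_paragraph(doc, s$text)
  }

  docx_add_heading(doc, "Composite score ranking", 2L)
  docx_add_table(doc, ranking_table(bundle$scores))
  docx_add_heading(doc, "Cluster membership", 2L)
  docx_add_table(doc, cluster_table(bundle$clusters, bundle$scores))
  if (length(bundle$correlations)) {
    docx_add_heading(doc, "Correlations", 2L)
    docx_add_table(doc, correlation_table(bundle$correlations))
  }
  if (length(bundle$tests)) {
    docx_add_heading(doc, "Statistical tests", 2L)
    docx_add_table(doc, test_table(bundle$tests))
  }
  if (length(figures)) {
    docx_add_heading(doc, "Figures", 2L)
    for (f in figures) docx_add_image(doc, f$path, caption = f$caption)
  }
  docx_save(doc, path)
  hp_log("INFO", "report", "wrote %s", path)
  path
}
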