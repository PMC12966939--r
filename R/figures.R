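# Figure rendering for the report: score bar chart, cluster scatter,
# correlation heatmap. Rendering is deterministic for a given bundle (fixed
# device size and DPI), so repeated runs embed identical images.

FIG_DPI <- 150
FIG_WIDTH_IN <- 8
FIG_HEIGHT_IN <- 6

save_plot <- function(plot, path) {
  type <- if (capabilities("cairo")) "cairo-png" else getOption("bitmapType")
  grDevices::png(path, width = FIG_WIDTH_IN * FIG_DPI, height = FIG_HEIGHT_IN * FIG_DPI,
                 res = FIG_DPI, type = type)
  print(plot)
  grDevices::dev.off()
  if (!file.exists(path) || file.size(path) == 0)
    hp_stop("io_error", "failed to write figure %s", path)
  path
}

score_bar_chart <- function(scores) {
  df <- as.data.frame(scores)
  df$unit <- factor(df$unit, levels = rev(df$unit))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$unit)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "Composite score (0-100)", y = NULL,
                  title = "Unit ranking by composite health score") +
    ggplot2::theme_minimal(base_size = 11)
}

cluster_scatter <- function(clusters, scores) {
  z <- scores$z_matrix
  # all standardised columns share the same variance; the first two columns
  # are the deterministic tie-break
  vars <- apply(z, 2, stats::var)
  axes <- order(-vars)[1:2]
  df <- data.frame(x = z[, axes[1]], y = z[, axes[2]],
                   cluster = factor(clusters$labels),
                   unit = scores$unit_names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = paste0(colnames(z)[axes[1]], " (z)"),
                  y = paste0(colnames(z)[axes[2]], " (z)"),
                  colour = "Cluster",
                  title = "Unit stratification by k-means") +
    ggplot2::theme_minimal(base_size = 11)
}

correlation_heatmap <- function(correlations) {
  vars <- unique(unlist(lapply(correlations, function(cc) c(cc$var_x, cc$var_y))))
  df <- do.call(rbind, lapply(correlations, function(cc)
    data.frame(x = c(cc$var_x, cc$var_y), y = c(cc$var_y, cc$var_x), r = cc$r)))
  df <- rbind(df, data.frame(x = vars, y = vars, r = 1))
  df$x <- factor(df$x, levels = vars)
  df$y <- factor(df$y, levels = rev(vars))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = fmt_num(.data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Pearson correlation between indicators") +
    ggplot2::theme_minimal(base_size = 11) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render the report figures for an analysis bundle
#'
#' Writes up to three PNGs: a horizontal bar chart of composite scores sorted
#' descending, a 2-D scatter of units coloured by cluster on the two
#' highest-variance standardised indicators (skipped with a warning when
#' fewer than two indicators exist), and a correlation heatmap annotated with
#' r (skipped when no correlations were computed).
#'
#' @param bundle An `analysis_bundle`.
#' @param outdir Output directory (created if needed).
#' @return List of figure artifacts: `kind`, `path`, `caption`.
#' @export
render_figures <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, mode = 2) != 0)
    hp_stop("io_error", "output directory %s is not writable", outdir)
  figs <- list()
  figs[[length(figs) + 1L]] <- list(
    kind = "score_bar_chart",
    path = save_plot(score_bar_chart(bundle$scores),
                     file.path(outdir, "fig_scores.png")),
    caption = "Unit-wise ranking based on the composite health score.")
  if (ncol(bundle$scores$z_matrix) >= 2L) {
    figs[[length(figs) + 1L]] <- list(
      kind = "cluster_scatter",
      path = save_plot(cluster_scatter(bundle$clusters, bundle$scores),
                       file.path(outdir, "fig_clusters.png")),
      caption = sprintf("Unit clustering (k = %d) on standardised indicators.",
                        bundle$clusters$k))
  } else {
    hp_warn("cluster scatter skipped: needs at least 2 indicators")
  }
  if (length(bundle$correlations) > 0L) {
    figs[[length(figs) + 1L]] <- list(
      kind = "correlation_heatmap",
      path = save_plot(correlation_heatmap(bundle$correlations),
                       file.path(outdir, "fig_correlations.png")),
      caption = "Pearson correlation between selected indicators.")
  }
  figs
}
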