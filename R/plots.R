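#' Volcano plot of pull-down enrichment
#'
#' log2 enrichment against -log10 q-value, with guide lines at the
#' significance threshold and at 2x enrichment.
#'
#' @param enrichment Tibble from [enrichment_table()].
#' @param q_cutoff Horizontal guide (default 0.05).
#' @param fold_cutoff Vertical guides at +/- log2(fold_cutoff) (default 2).
#' @return A ggplot object.
#' @export
plot_volcano <- function(enrichment, q_cutoff = 0.05, fold_cutoff = 2) {
  df <- dplyr::mutate(enrichment,
                      neg_log10_q = -log10(pmax(.data$q_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_enrichment,
                                   y = .data$neg_log10_q)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag_2x),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(q_cutoff), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fold_cutoff),
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 enrichment (tagged / control)",
                  y = "-log10 q-value") +
    ggplot2::theme_classic()
}

#' Scatter of a localization scene
#'
#' x-y scatter of localizations coloured by channel; a quick visual check
#' of simulated or loaded scenes.
#'
#' @param locs Localization tibble.
#' @param cells Optional vector of cell ids to restrict to.
#' @return A ggplot object.
#' @export
plot_scene <- function(locs, cells = NULL) {
  if (!is.null(cells)) locs <- locs[locs$cell_id %in% cells, ]
  ggplot2::ggplot(locs, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$channel)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c(sRNA = "red3",
                                            mRNA = "green4")) +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_classic()
}

#' Copy number versus colocalization, per condition
#'
#' The summary presentation of a pipeline run: mean sRNA copies per cell
#' against the colocalization percentage, one point per condition, with
#' replicate-SD error bars when available.
#'
#' @param object A `pipeline_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pipeline_report <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_srna_copies,
                                   y = 100 * .data$coloc_fraction,
                                   colour = .data$condition)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * (.data$coloc_fraction -
                                   .data$coloc_sd_replicates),
                   ymax = 100 * (.data$coloc_fraction +
                                   .data$coloc_sd_replicates)),
      width = 0, na.rm = TRUE) +
    ggplot2::geom_hline(
      yintercept = 100 * unique(df$baseline_fraction), linetype = 3) +
    ggplot2::labs(x = "sRNA copies per cell",
                  y = "colocalization (%)") +
    ggplot2::theme_classic()
}

#' Heatmap of a copy-number reference matrix
#'
#' @param object A `reference_matrix`.
#' @param max_n Largest spot count row to show (default 4 times the
#'   single-molecule mean).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reference_matrix <- function(object, max_n = NULL, ...) {
  max_n <- max_n %||% min(object$n_max, ceiling(4 * object$model$mean))
  df <- expand.grid(n = 0:max_n, k = seq_len(object$k_max))
  df$p <- object$entries[cbind(df$n + 1, df$k)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$n,
                                   fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "P(n | k)") +
    ggplot2::labs(x = "RNA copies k", y = "localization spots n") +
    ggplot2::theme_classic()
}
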