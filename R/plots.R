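#' Scatter plot of element NRS against significance
#'
#' Volcano-style view of scored elements, coloured by enrichment class.
#'
#' @param records Scored tibble from [score_elements()].
#' @param config Optional [test_config()] to draw the thresholds.
#' @return A ggplot object.
#' @export
plot_nrs_scatter <- function(records, config = attr(records, "config")) {
  p <- ggplot2::ggplot(records, ggplot2::aes(
    x = .data$nrs, y = -log10(pmax(.data$p_value, 1e-300)),
    colour = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(
      nuclear = "#c0392b", cytoplasmic = "#2980b9", neutral = "grey60")) +
    ggplot2::labs(x = "NRS (log2 nuclear/cytoplasmic CPM)",
                  y = expression(-log[10] ~ p), colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(config)) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(-config$nrs_cut, config$nrs_cut),
                          linetype = "dashed", colour = "grey40") +
      ggplot2::geom_hline(yintercept = -log10(config$p_cut),
                          linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a transcript NRS profile
#'
#' Averaged per-nucleotide NRS along the transcript, with peaks overlaid
#' when supplied.
#'
#' @param object An `nrs_profile`.
#' @param peaks Optional peak tibble for this transcript.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nrs_profile <- function(object, peaks = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$averaged)) +
    ggplot2::geom_line(colour = "grey20") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "position (nt)", y = "averaged NRS",
                  title = object$transcript_id) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = peaks,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf,
                   ymax = Inf, fill = .data$class),
      alpha = 0.2, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(values = c(nuclear = "#c0392b",
                                            cytoplasmic = "#2980b9"))
  }
  p
}

#' Epoch curves of a fitted localization model
#'
#' @param object A `loc_model`.
#' @param ... Unused.
#' @return A ggplot object with accuracy and loss panels over epochs.
#' @export
autoplot.loc_model <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(-"epoch", names_to = c("split", "metric"),
                        names_sep = "_", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' ROC and precision-recall curves of an evaluation
#'
#' @param object A `loc_eval`.
#' @param ... Unused.
#' @return A ggplot object (ROC and PR side by side).
#' @export
autoplot.loc_eval <- function(object, ...) {
  roc <- mutate(object$roc, panel = sprintf("ROC (AUC %.3f)", object$auroc))
  pr <- mutate(object$pr, panel = sprintf("PR (AUC %.3f)", object$auprc))
  df <- bind_rows(
    tibble(x = roc$fpr, y = roc$tpr, panel = roc$panel),
    tibble(x = pr$recall, y = pr$precision, panel = pr$panel)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "#c0392b") +
    ggplot2::facet_wrap(~ .data$panel) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Metagene plot around peak centers
#'
#' @param mg Tibble from [metagene()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(mg) {
  ggplot2::ggplot(mg, ggplot2::aes(x = .data$offset, y = .data$mean_nrs,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(nuclear = "#c0392b",
                                            cytoplasmic = "#2980b9")) +
    ggplot2::labs(x = "offset from peak center (nt)", y = "mean NRS",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Knockdown shift volcano with density colouring
#'
#' @param records Tibble from [shift_test()].
#' @param delta_cut,p_cut Thresholds to draw.
#' @param bins Bins per axis for the density grid.
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, delta_cut = 0.58, p_cut = 0.05, bins = 50L) {
  pts <- volcano_table(records, bins = bins)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$delta, y = .data$neg_log10_p,
                                    colour = .data$density)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_viridis_c(trans = "log10") +
    ggplot2::geom_vline(xintercept = c(-delta_cut, delta_cut),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = expression(Delta ~ log[2] ~ FC),
                  y = expression(-log[10] ~ p), colour = "genes/bin") +
    ggplot2::theme_minimal()
}

#' Base-composition contrast plot
#'
#' @param contrast Tibble from [composition_contrast()].
#' @return A ggplot object of per-base frequency differences.
#' @export
plot_composition <- function(contrast) {
  ggplot2::ggplot(contrast, ggplot2::aes(x = .data$base, y = .data$diff,
                                         fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "frequency difference (set A - set B)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
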