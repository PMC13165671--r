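# ggplot2 visualisations of training, calibration and concept results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot training history
#' @param object A `senn_model`.
#' @param ... Unused.
#' @return A ggplot of loss and validation AUC trajectories.
#' @export
autoplot.senn_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history[, c("epoch", "loss", "val_auc")],
                           -"epoch", names_to = "series")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training dynamics") +
    ggplot2::theme_minimal()
}

#' Reliability diagram of a run
#' @param object A `senn_run`.
#' @param ... Unused.
#' @return A ggplot of per-bin mean predicted probability versus observed PD
#'   fraction on calibrated test windows.
#' @export
autoplot.senn_run <- function(object, ...) {
  tab <- dplyr::filter(object$reliability, .data$n > 0L)
  ggplot2::ggplot(tab, ggplot2::aes(.data$mean_prob, .data$frac_pos)) +
    ggplot2::geom_abline(linetype = 2L, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean predicted probability",
                  y = "observed PD fraction",
                  title = "Reliability (calibrated test windows)") +
    ggplot2::theme_minimal()
}

#' Concept discriminative-power chart
#' @param object A `concept_report`.
#' @param ... Unused.
#' @return A ggplot of the per-concept class gap, ranked.
#' @export
autoplot.concept_report <- function(object, ...) {
  st <- object$stats
  st$concept <- factor(st$concept, levels = rev(object$ranking))
  ggplot2::ggplot(st, ggplot2::aes(.data$delta, .data$concept)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(Delta[k]~"(absolute contribution gap)"),
                  y = "concept",
                  title = "Concept discriminative power") +
    ggplot2::theme_minimal()
}

#' Concept-by-sensor-group correlation heatmap
#' @param report A `concept_report` computed with raw windows.
#' @return A ggplot heatmap of Pearson correlations.
#' @export
plot_concept_sensor_map <- function(report) {
  stopifnot(!is.null(report$sensor_corr))
  df <- as.data.frame(as.table(report$sensor_corr))
  names(df) <- c("concept", "group", "r")
  df$concept <- as.integer(df$concept)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, factor(.data$concept),
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "concept",
                  title = "Concept x anatomical sensor-group correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
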