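#' Plot a PVR trace
#'
#' Pressure-offset waveform over time, with ground-truth feet/peaks marked
#' when available.
#'
#' @param object A `pvr_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pvr_trace <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$t_ms / 1000,
                                    y = .data$pressure_mmhg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "pressure offset (mmHg)",
                  title = sprintf("PVR trace %s", attr(object, "limb_id")))
  gt <- attr(object, "ground_truth")
  if (!is.null(gt)) {
    marks <- tidyr::pivot_longer(
      gt[gt$complete, c("foot_ms", "peak_ms")],
      cols = dplyr::everything(),
      names_to = "fiducial", values_to = "t_ms"
    )
    p <- p + ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$t_ms / 1000,
                   colour = .data$fiducial),
      linetype = "dotted", alpha = 0.5
    )
  }
  p
}

#' Plot an ROC curve
#'
#' @param object A [pvr_roc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pvr_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$spec, y = .data$sens)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUC %.2f (%s)", object$auc, object$direction)
    )
}

#' Morphology distribution by GLASS stage
#'
#' Stacked per-stage proportions of the four morphology grades in a graded
#' cohort, the pattern linking visual PVR severity to angiographic disease
#' stage.
#'
#' @param graded Cohort tibble with a `morphology` column
#'   ([classify_morphology()]).
#' @return A ggplot object.
#' @export
plot_morphology_by_glass <- function(graded) {
  ggplot2::ggplot(graded, ggplot2::aes(x = .data$glass,
                                       fill = .data$morphology)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = "GLASS stage", y = "fraction of limbs",
                  fill = "PVR morphology")
}
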