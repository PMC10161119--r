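## ggplot2 graphics for QA sessions, DVH curves and banded DVHs.

#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dose_cGy, y = .data$volume_pct,
                               colour = .data$structure)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose [cGy(RBE)]", y = "Volume [%]",
                  colour = "Structure") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot a banded DVH with optional nominal curves
#'
#' @param object A `banded_dvh` tibble.
#' @param prescription_cGy Optional prescription; adds vertical reference
#'   lines at 95% and 100% of prescription.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.banded_dvh <- function(object, prescription_cGy = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_cGy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$vol_min,
                                      ymax = .data$vol_max,
                                      fill = .data$structure), alpha = 0.35) +
    ggplot2::labs(x = "Dose [cGy(RBE)]", y = "Volume [%]",
                  fill = "Structure", colour = "Structure") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
  if ("vol_nominal" %in% names(object) && !all(is.na(object$vol_nominal))) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$vol_nominal, colour = .data$structure),
      linetype = "dashed")
  }
  if (!is.null(prescription_cGy)) {
    p <- p +
      ggplot2::geom_vline(xintercept = 0.95 * prescription_cGy,
                          colour = "blue", linetype = "dotted") +
      ggplot2::geom_vline(xintercept = prescription_cGy,
                          colour = "darkgreen", linetype = "dotted")
  }
  p
}

#' Scatter plot of recorded-minus-measured QA deltas
#'
#' @param qa A `qa_session`.
#' @return A ggplot object.
#' @export
plot_qa_deltas <- function(qa) {
  pairs <- match_spots(qa)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$delta_x_mm,
                                      y = .data$delta_y_mm)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = expression(Delta * x ~ "[mm] (recorded - measured)"),
      y = expression(Delta * y ~ "[mm] (recorded - measured)"),
      title = sprintf("Spot position agreement, gantry %g deg",
                      attr(qa, "gantry_angle_deg") %||% NA)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
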