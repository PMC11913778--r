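#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: the IV plot of an
#' `egaba_fit` (corrected current-voltage points, fitted lines, RMP and
#' E_GABAAR markers), a raster plot of a `spike_raster`, the membrane-
#' potential density of a `vm_stats`, and the estimated-versus-true
#' reversal curve of a `bias_curve`.
#'
#' @param object The object to plot.
#' @param max_trials Raster plots show at most this many trials.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gabashunt-autoplot
NULL

#' @rdname gabashunt-autoplot
#' @method autoplot egaba_fit
#' @export
autoplot.egaba_fit <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$vm_mV, y = .data$i_pA,
                                    colour = .data$sweep)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(
      data = object$lines,
      ggplot2::aes(slope = .data$slope_nS, intercept = .data$intercept_pA,
                   colour = .data$sweep)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::annotate("point", x = object$rmp_mV, y = 0, shape = 21,
                      size = 3, fill = "white") +
    ggplot2::annotate("point", x = object$egaba_mV,
                      y = object$lines$slope_nS[1] * object$egaba_mV +
                        object$lines$intercept_pA[1],
                      shape = 21, size = 3, fill = "black") +
    ggplot2::labs(x = "corrected membrane potential (mV)",
                  y = "current (pA)",
                  title = sprintf("RMP %.1f mV, E_GABAAR %.1f mV, DF %.1f mV, g %.1f nS",
                                  object$rmp_mV, object$egaba_mV,
                                  object$df_mV, object$g_gaba_nS)) +
    ggplot2::theme_minimal()
}

#' @rdname gabashunt-autoplot
#' @method autoplot spike_raster
#' @export
autoplot.spike_raster <- function(object, max_trials = 50, ...) {
  ev <- tibble::as_tibble(object)
  ev <- ev[ev$trial <= max_trials, , drop = FALSE]
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$t_ms, y = .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 1.2) +
    ggplot2::facet_wrap(~trial, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "time from stimulus (ms)", y = "neuron",
                  title = raster_condition(object)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 6),
                   panel.spacing = ggplot2::unit(0, "pt"))
}

#' @rdname gabashunt-autoplot
#' @method autoplot vm_stats
#' @export
autoplot.vm_stats <- function(object, ...) {
  ggplot2::ggplot(object$density,
                  ggplot2::aes(x = .data$vm_mV, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mean_vm_mV, linetype = 2) +
    ggplot2::labs(x = "membrane potential (mV)", y = "probability density",
                  title = sprintf("mean Vm %.1f mV, mean |dV/dt| %.2f mV/ms",
                                  object$mean_vm_mV,
                                  object$mean_abs_dvdt_mV_per_ms)) +
    ggplot2::theme_minimal()
}

#' @rdname gabashunt-autoplot
#' @method autoplot bias_curve
#' @export
autoplot.bias_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$egaba_true_mV, y = .data$egaba_est_mV,
                               colour = factor(.data$correction))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "true E_GABAAR (mV)", y = "estimated E_GABAAR (mV)",
                  colour = "Rs correction") +
    ggplot2::theme_minimal()
}
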