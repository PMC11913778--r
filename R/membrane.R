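#' Membrane and recording properties from a seal-test step
#'
#' Estimates the series resistance (Rs), input resistance and membrane
#' resistance (Rm) from the current response to a small voltage step
#' (by default -10 mV) in voltage clamp. Rs is estimated two ways and the
#' numerical average is reported: (i) from the peak of the current transient
#' at the step edge, and (ii) from the peak obtained by fitting a single
#' exponential to the decay of the transient (default fit window 0.1-10 ms
#' after the edge) and extrapolating back to the step onset, which removes
#' the bias caused by the finite sampling of a fast transient. The input
#' resistance comes from the steady-state current change and
#' `Rm = R_input - Rs`.
#'
#' Perforated-patch recordings are only usable once Rs has stabilised below
#' 100 MOhm; the returned `rs_acceptable` flag applies that criterion.
#'
#' @param seal_sweep A VC sweep containing a single voltage step with pre- and
#'   post-step baselines.
#' @param step_mV Step amplitude in mV (sign as delivered; default -10).
#' @param expfit_window_ms Fit window after the step edge for the exponential,
#'   `c(lo, hi)` in ms.
#' @param rs_limit_MOhm Acceptance threshold for Rs (MOhm).
#' @return A one-row tibble: `rs_peak_MOhm`, `rs_expfit_MOhm`, `rs_MOhm`
#'   (their mean), `r_input_MOhm`, `rm_MOhm`, `tau_ms` (fitted transient time
#'   constant), `rs_acceptable`, `steady_state_ok` (FALSE when the
#'   steady-state window is shorter than 3 fitted time constants).
#' @export
estimate_membrane_properties <- function(seal_sweep, step_mV = -10,
                                         expfit_window_ms = c(0.1, 10),
                                         rs_limit_MOhm = 100) {
  assert_mode(seal_sweep, "VC", "estimate_membrane_properties()")
  cmd <- seal_sweep$command
  cur <- seal_sweep$recorded
  dt_ms <- sweep_dt(seal_sweep) * 1e3

  hold <- cmd[1]
  in_step <- abs(cmd - hold) > abs(step_mV) / 2
  if (!any(in_step))
    abort("no voltage step found in the seal-test sweep.",
          class = "gabashunt_fit_error")
  i_on <- which(in_step)[1]
  i_off <- i_on + which(!in_step[i_on:length(in_step)])[1] - 2
  if (is.na(i_off)) i_off <- length(cmd)
  step_actual <- mean(cmd[i_on:i_off]) - hold
  if (i_on < 5) abort("seal-test sweep lacks a pre-step baseline.",
                      class = "gabashunt_fit_error")

  # baseline: latter half of the pre-step epoch
  i_base <- mean(cur[ceiling(i_on / 2):(i_on - 1)])
  # steady state: last quarter of the step epoch
  n_step <- i_off - i_on + 1
  ss_idx <- (i_off - floor(n_step / 4)):i_off
  i_ss <- mean(cur[ss_idx])

  d_ss <- i_ss - i_base
  if (abs(d_ss) < .Machine$double.eps)
    abort("no steady-state current change: cannot estimate input resistance.",
          class = "gabashunt_fit_error")
  r_input <- abs(step_actual / d_ss) * 1e3  # mV / pA -> GOhm -> MOhm

  # peak transient within the first 2 ms after the edge
  n_peak <- max(1, min(n_step, round(2 / dt_ms)))
  seg <- cur[i_on:(i_on + n_peak - 1)] - i_base
  i_pk <- seg[which.max(abs(seg))]
  if (abs(i_pk) <= abs(d_ss) * 1.01)
    abort("no detectable current transient at the step edge.",
          class = "gabashunt_fit_error")
  rs_peak <- abs(step_actual / i_pk) * 1e3

  # exponential fit to the transient decay, extrapolated to the edge
  t_rel <- (seq_len(n_step) - 1) * dt_ms
  fit_sel <- t_rel >= expfit_window_ms[1] & t_rel <= expfit_window_ms[2]
  y <- cur[i_on:i_off][fit_sel] - i_ss
  tt <- t_rel[fit_sel]
  sgn <- sign(i_pk - d_ss)
  pos <- sgn * y > 0
  if (sum(pos) < 3)
    abort("too few samples in the exponential fit window.",
          class = "gabashunt_fit_error")
  lf <- lm(log(sgn * y[pos]) ~ tt[pos])
  a0 <- exp(coef(lf)[[1]]) * sgn
  tau <- -1 / coef(lf)[[2]]
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ a * exp(-tt / tau), start = list(a = a0, tau = tau),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    a0 <- coef(fit)[["a"]]
    tau <- coef(fit)[["tau"]]
  }
  if (!is.finite(tau) || tau <= 0)
    abort("exponential fit to the step transient failed.",
          class = "gabashunt_fit_error")
  i_pk_fit <- a0 + d_ss  # extrapolated transient amplitude at the edge
  rs_expfit <- abs(step_actual / i_pk_fit) * 1e3

  steady_ok <- (min(ss_idx) - i_on) * dt_ms >= 3 * tau
  if (!steady_ok)
    warn("steady-state window begins earlier than 3 fitted time constants after the step edge.")

  rs <- mean(c(rs_peak, rs_expfit))
  tibble::tibble(rs_peak_MOhm = rs_peak, rs_expfit_MOhm = rs_expfit,
                 rs_MOhm = rs, r_input_MOhm = r_input,
                 rm_MOhm = r_input - rs, tau_ms = tau,
                 rs_acceptable = rs < rs_limit_MOhm,
                 steady_state_ok = steady_ok)
}
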