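#' Estimate the GABA-A reversal potential from paired voltage ramps
#'
#' Implements the ramp-protocol estimator of the synaptic GABA-A reversal
#' potential (E_GABAAR). Two consecutive voltage ramps are delivered in
#' voltage clamp: a baseline ramp sampling the neuron's intrinsic membrane
#' currents and a light ramp during a light-evoked synaptic GABA-A
#' conductance. Both current traces are series-resistance corrected (see
#' [correct_series_resistance()]), the first and last `edge_exclusion_ms` of
#' each ramp are excluded, optional crop windows remove contaminated
#' stretches, and a straight line is fitted to each current against the
#' corrected membrane potential. The zero crossing of the baseline line is
#' the resting membrane potential (RMP); the intersection of the two lines —
#' equivalently the zero crossing of the light-minus-baseline difference
#' line — is E_GABAAR; the slope of the difference line is the GABA-A
#' conductance in nS; the driving force is `DF = RMP - E_GABAAR`.
#'
#' @param baseline,light VC-mode sweeps sharing the same protocol; the light
#'   sweep carries the light-evoked conductance starting at the ramp onset.
#' @param rs_MOhm Series resistance used for offline correction (MOhm).
#' @param rs_fraction Fraction of Rs corrected for (default 0.9).
#' @param proto A [protocol()] (its `edge_exclusion_ms` is used).
#' @param crop Optional list of length-2 vectors; samples falling inside any
#'   interval are dropped before fitting. Intervals are interpreted in
#'   `crop_units`: `"time_s"` (sweep time) or `"vm_mV"` (corrected membrane
#'   potential). Cropping is deliberately an explicit input: in real
#'   recordings contaminated stretches (spikes, capacitance transients) are
#'   identified by eye.
#' @param crop_units Units of the crop intervals.
#' @param min_points Minimum IV points required in each fit.
#' @param ramp_window_s Optional `c(start, end)` of the ramp epoch in sweep
#'   time; auto-detected from the command waveform when `NULL`.
#' @return An object of class `egaba_fit` with elements `rmp_mV`, `egaba_mV`,
#'   `df_mV`, `g_gaba_nS`, `protocol`, `lines` (per-sweep slope/intercept in
#'   nS and pA), `data` (the IV points used), `n_points`,
#'   `fit_voltage_window_mV`. Use [glance()] for a one-row summary and
#'   [autoplot()] for the IV plot.
#' @examples
#' ses <- gen_iv_session(iv_truth(noise_pA = 0, rs_MOhm = 0), seed = 1)
#' fit <- fit_iv_ramp(ses$baseline, ses$light, rs_MOhm = 0)
#' glance(fit)
#' @export
fit_iv_ramp <- function(baseline, light, rs_MOhm, rs_fraction = 0.9,
                        proto = protocol("ramp"), crop = NULL,
                        crop_units = c("time_s", "vm_mV"),
                        min_points = 10, ramp_window_s = NULL) {
  crop_units <- match.arg(crop_units)
  assert_mode(baseline, "VC", "fit_iv_ramp()")
  assert_mode(light, "VC", "fit_iv_ramp()")
  if (nrow(baseline) != nrow(light) ||
      abs(sweep_dt(baseline) - sweep_dt(light)) > 1e-12)
    abort("baseline and light sweeps must share the same time base.",
          class = "gabashunt_shape_error")

  if (is.null(ramp_window_s)) ramp_window_s <- detect_ramp_window(baseline)

  pts <- dplyr::bind_rows(
    iv_points(baseline, rs_MOhm, rs_fraction, proto, ramp_window_s, "baseline"),
    iv_points(light, rs_MOhm, rs_fraction, proto, ramp_window_s, "light"))
  pts <- apply_crop(pts, crop, crop_units)

  fit_iv_lines(pts, protocol_label = "ramp", min_points = min_points)
}

# shared line-fitting core for ramp and step estimators
fit_iv_lines <- function(pts, protocol_label, min_points,
                         slope_tol_nS = 1e-8) {
  counts <- table(pts$sweep)
  if (length(counts) < 2 || any(counts < min_points))
    abort(sprintf("fewer than %d IV points remain after cropping.", min_points),
          class = "gabashunt_insufficient_data")

  fits <- pts |>
    dplyr::group_by(.data$sweep) |>
    dplyr::summarise(slope_nS = coef(lm(i_pA ~ vm_mV))[[2]],
                     intercept_pA = coef(lm(i_pA ~ vm_mV))[[1]],
                     n_points = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(reversal_mV = -.data$intercept_pA / .data$slope_nS)

  b <- fits[fits$sweep == "baseline", ]
  l <- fits[fits$sweep == "light", ]
  d_slope <- l$slope_nS - b$slope_nS
  d_int <- l$intercept_pA - b$intercept_pA
  if (abs(d_slope) < slope_tol_nS)
    abort("baseline and light IV lines are parallel: no intersection, cannot estimate E_GABAAR.",
          class = "gabashunt_no_intersection")

  rmp <- -b$intercept_pA / b$slope_nS
  egaba <- -d_int / d_slope
  out <- list(rmp_mV = rmp, egaba_mV = egaba, df_mV = rmp - egaba,
              g_gaba_nS = d_slope, protocol = protocol_label,
              g_flagged = d_slope < 0,
              lines = fits, data = pts,
              n_points = sum(fits$n_points),
              fit_voltage_window_mV = range(pts$vm_mV))
  class(out) <- "egaba_fit"
  out
}

iv_points <- function(sweep, rs_MOhm, rs_fraction, proto, ramp_window_s, label) {
  corr <- correct_series_resistance(sweep, rs_MOhm, rs_fraction)
  excl <- proto$edge_exclusion_ms / 1e3
  sel <- corr$time_s >= ramp_window_s[1] + excl &
    corr$time_s <= ramp_window_s[2] - excl
  tibble::tibble(sweep = label, time_s = corr$time_s[sel],
                 vm_mV = corr$vm_mV[sel], i_pA = corr$recorded[sel])
}

apply_crop <- function(pts, crop, crop_units) {
  if (is.null(crop) || length(crop) == 0) return(pts)
  key <- if (crop_units == "time_s") pts$time_s else pts$vm_mV
  drop <- rep(FALSE, nrow(pts))
  for (iv in crop) drop <- drop | (key >= iv[1] & key <= iv[2])
  pts[!drop, , drop = FALSE]
}

# longest strictly increasing run of the command waveform
detect_ramp_window <- function(sweep) {
  up <- diff(sweep$command) > 0
  if (!any(up)) abort("no ramp found in the command waveform.")
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- which(r$values)[which.max(r$lengths[r$values])]
  c(sweep$time_s[starts[k]], sweep$time_s[ends[k] + 1])
}

#' Estimate the GABA-A reversal potential from a voltage-step protocol
#'
#' The step protocol clamps the neuron at each voltage of a grid (by default
#' -130 to -30 mV in 10 mV increments, 500 ms steps) and delivers a light
#' pulse during each step. Per step, the membrane current is measured
#' immediately before the light pulse (baseline) and again at a fixed latency
#' after light onset — 20 ms by default, the peak of the GABA-A conductance.
#' The resulting baseline and light IV points are series-resistance corrected
#' and E_GABAAR is estimated exactly as for the ramp protocol. When
#' `t_ramp_ms` is supplied (the latency at which the ramp-protocol E_GABAAR
#' was measured in the same cell), a second estimate is computed there and
#' the difference between the two is returned as `gabab_stability_mV`, a
#' diagnostic for E_GABAAR stability and GABA-B contamination.
#'
#' @param steps List of VC sweeps, one per grid voltage, each with light
#'   metadata.
#' @param rs_MOhm,rs_fraction Series-resistance correction settings.
#' @param proto A [protocol()] of kind `"step"`.
#' @param t_light_ms Measurement latency after light onset (ms).
#' @param t_ramp_ms Optional second latency for the stability diagnostic.
#' @param baseline_ms Width of the pre-light baseline window (ms).
#' @param measure_ms Averaging window around each measurement time (ms).
#' @param min_points Minimum usable steps.
#' @return An `egaba_fit` (protocol `"step20ms"`), with
#'   `gabab_stability_mV` and `egaba_ramp_time_mV` when `t_ramp_ms` is given,
#'   and a `qc` tibble flagging missing grid voltages.
#' @export
fit_iv_step <- function(steps, rs_MOhm, rs_fraction = 0.9,
                        proto = protocol("step"), t_light_ms = 20,
                        t_ramp_ms = NULL, baseline_ms = 5, measure_ms = 1,
                        min_points = 4) {
  if (length(steps) < min_points)
    abort("too few step sweeps.", class = "gabashunt_insufficient_data")
  measure_at <- function(t_ms) {
    purrr::map_dfr(steps, function(sw) {
      assert_mode(sw, "VC", "fit_iv_step()")
      lt <- sweep_light(sw)
      if (is.na(lt$onset_s))
        abort("step sweep lacks light metadata.")
      base_sel <- sw$time_s >= lt$onset_s - baseline_ms / 1e3 &
        sw$time_s < lt$onset_s
      m_t <- lt$onset_s + t_ms / 1e3
      meas_sel <- abs(sw$time_s - m_t) <= measure_ms / 2e3
      v_step <- mean(sw$command[base_sel])
      tibble::tibble(v_step_mV = v_step,
                     i_base_pA = mean(sw$recorded[base_sel]),
                     i_light_pA = mean(sw$recorded[meas_sel]))
    })
  }
  grid <- measure_at(t_light_ms)
  missing_v <- setdiff(round(proto$step_grid_mV), round(grid$v_step_mV))
  if (length(missing_v) > 0)
    warn(sprintf("step grid voltages missing from the data: %s",
                 paste(missing_v, collapse = ", ")))

  pts_at <- function(grid) {
    dplyr::bind_rows(
      tibble::tibble(sweep = "baseline", time_s = NA_real_,
                     vm_mV = grid$v_step_mV - grid$i_base_pA * rs_fraction * rs_MOhm * 1e-3,
                     i_pA = grid$i_base_pA),
      tibble::tibble(sweep = "light", time_s = NA_real_,
                     vm_mV = grid$v_step_mV - grid$i_light_pA * rs_fraction * rs_MOhm * 1e-3,
                     i_pA = grid$i_light_pA))
  }
  fit <- fit_iv_lines(pts_at(grid), protocol_label = "step20ms",
                      min_points = min_points)
  fit$qc <- tibble::tibble(missing_grid_mV = list(missing_v),
                           saturated = any(abs(grid$i_light_pA) > 2e4))
  if (!is.null(t_ramp_ms)) {
    fit2 <- fit_iv_lines(pts_at(measure_at(t_ramp_ms)),
                         protocol_label = "stepAtRampTime",
                         min_points = min_points)
    fit$egaba_ramp_time_mV <- fit2$egaba_mV
    fit$gabab_stability_mV <- fit$egaba_mV - fit2$egaba_mV
  }
  fit
}

#' @export
print.egaba_fit <- function(x, ...) {
  cat(sprintf("<egaba_fit: %s protocol>\n", x$protocol))
  cat(sprintf("  RMP      %8.2f mV\n", x$rmp_mV))
  cat(sprintf("  E_GABAAR %8.2f mV\n", x$egaba_mV))
  cat(sprintf("  DF       %8.2f mV\n", x$df_mV))
  cat(sprintf("  g_GABA   %8.2f nS%s\n", x$g_gaba_nS,
              if (isTRUE(x$g_flagged)) "  [flag: negative conductance]" else ""))
  cat(sprintf("  n points %d over %.1f to %.1f mV\n", x$n_points,
              x$fit_voltage_window_mV[1], x$fit_voltage_window_mV[2]))
  invisible(x)
}

#' Tidy and summarise reversal-potential fits
#'
#' `tidy()` returns the fitted IV line per sweep (slope in nS, intercept in
#' pA, zero-crossing voltage); `glance()` returns the one-row estimate table
#' (`rmp_mV`, `egaba_mV`, `df_mV`, `g_gaba_nS`, `protocol`, `n_points`).
#'
#' @param x An `egaba_fit`.
#' @param ... Unused.
#' @method tidy egaba_fit
#' @export
tidy.egaba_fit <- function(x, ...) x$lines

#' @rdname tidy.egaba_fit
#' @method glance egaba_fit
#' @export
glance.egaba_fit <- function(x, ...) {
  tibble::tibble(rmp_mV = x$rmp_mV, egaba_mV = x$egaba_mV, df_mV = x$df_mV,
                 g_gaba_nS = x$g_gaba_nS, protocol = x$protocol,
                 n_points = x$n_points, g_flagged = x$g_flagged)
}
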