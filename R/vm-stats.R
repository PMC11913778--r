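#' Membrane-potential statistics from a continuous current-clamp recording
#'
#' Summarises spontaneous activity recorded in current clamp: samples more
#' depolarized than `exclude_above_mV` (default -40 mV) are removed to avoid
#' distortion by action potentials, the mean membrane potential and a
#' Gaussian kernel-density estimate over the remaining samples are computed,
#' and the level of background synaptic activity is quantified as the mean
#' modulus of the first derivative dV/dt (mV/ms). For the derivative,
#' samples within `ap_window_ms` of an upward crossing of the exclusion
#' threshold are removed and the derivative is winsorized at the
#' `winsor` percentiles before averaging.
#'
#' @param ic_trace An IC-mode [sweep_tbl()]: `recorded` is Vm in mV.
#' @param exclude_above_mV Spike-exclusion threshold (mV).
#' @param winsor Winsorization probabilities for dV/dt, `c(lo, hi)`.
#' @param ap_window_ms Half-width of the exclusion window around threshold
#'   crossings (ms).
#' @param bw Kernel bandwidth: `"scott"` (default) or a numeric value in mV.
#' @param min_duration_s Shorter traces raise an insufficient-data error.
#' @return A list of class `vm_stats`: `mean_vm_mV`, `density` (tibble
#'   `vm_mV`, `density`), `mean_abs_dvdt_mV_per_ms`, `n_samples`,
#'   `n_excluded`, `duration_s`.
#' @export
vm_statistics <- function(ic_trace, exclude_above_mV = -40,
                          winsor = c(0.01, 0.99), ap_window_ms = 2,
                          bw = "scott", min_duration_s = 10) {
  assert_mode(ic_trace, "IC", "vm_statistics()")
  dt_s <- sweep_dt(ic_trace)
  vm <- ic_trace$recorded
  dur <- dt_s * length(vm)
  if (dur < min_duration_s)
    abort(sprintf("trace is %.1f s long; at least %.0f s are required.",
                  dur, min_duration_s),
          class = "gabashunt_insufficient_data")

  keep <- vm <= exclude_above_mV
  vm_kept <- vm[keep]
  if (length(vm_kept) < 100)
    abort("almost all samples exceed the exclusion threshold.",
          class = "gabashunt_insufficient_data")
  bw_val <- if (identical(bw, "scott")) stats::bw.nrd(vm_kept) else bw
  if (!is.finite(bw_val) || bw_val <= 0) bw_val <- 0.1  # degenerate spread
  den <- density(vm_kept, bw = bw_val)

  dt_ms <- dt_s * 1e3
  dvdt <- diff(vm) / dt_ms
  # drop derivative samples near upward threshold crossings (action potentials)
  up <- which(vm[-1] > exclude_above_mV & vm[-length(vm)] <= exclude_above_mV)
  if (length(up) > 0) {
    w <- ceiling(ap_window_ms / dt_ms)
    bad <- unique(unlist(lapply(up, function(i)
      max(1, i - w):min(length(dvdt), i + w))))
    dvdt <- dvdt[-bad]
  }
  dvdt <- dvdt[is.finite(dvdt)]
  qs <- quantile(dvdt, winsor, names = FALSE)
  dvdt_w <- pmin(pmax(dvdt, qs[1]), qs[2])

  structure(list(mean_vm_mV = mean(vm_kept),
                 density = tibble::tibble(vm_mV = den$x, density = den$y),
                 bw_mV = bw_val,
                 mean_abs_dvdt_mV_per_ms = mean(abs(dvdt_w)),
                 n_samples = length(vm_kept),
                 n_excluded = sum(!keep),
                 duration_s = dur),
            class = "vm_stats")
}

#' @export
print.vm_stats <- function(x, ...) {
  cat("<vm_stats>\n")
  cat(sprintf("  mean Vm       %8.2f mV (%d samples, %d excluded > threshold)\n",
              x$mean_vm_mV, x$n_samples, x$n_excluded))
  cat(sprintf("  mean |dV/dt|  %8.3f mV/ms\n", x$mean_abs_dvdt_mV_per_ms))
  cat(sprintf("  duration      %8.1f s\n", x$duration_s))
  invisible(x)
}

#' @rdname tidy.egaba_fit
#' @method glance vm_stats
#' @export
glance.vm_stats <- function(x, ...) {
  tibble::tibble(mean_vm_mV = x$mean_vm_mV,
                 mean_abs_dvdt_mV_per_ms = x$mean_abs_dvdt_mV_per_ms,
                 n_samples = x$n_samples, n_excluded = x$n_excluded,
                 duration_s = x$duration_s)
}

#' Classify the polarity of light-evoked GABAergic responses
#'
#' Averages the membrane-potential response across current-clamp sweeps with
#' an optogenetic light pulse, normalizes to the mean potential during the
#' 100 ms preceding the pulse, and takes the mean normalized potential over
#' the 100 ms following the pulse. A strictly positive mean is classified as
#' depolarizing, otherwise hyperpolarizing (a mean of exactly zero is the
#' boundary case and is labelled hyperpolarizing).
#'
#' @param ic_sweeps List of IC sweeps with light metadata (typically 15).
#' @param pre_ms,post_ms Baseline and response window lengths (ms).
#' @param after `"offset"` (default): the response window starts at the end
#'   of the light pulse; `"onset"`: at light onset.
#' @return A list of class `polarity_result`: `mean_post_light_mV`, `label`,
#'   `n_sweeps`, `mean_trace` (tibble of the averaged, baseline-normalized
#'   trace).
#' @export
classify_polarity <- function(ic_sweeps, pre_ms = 100, post_ms = 100,
                              after = c("offset", "onset")) {
  after <- match.arg(after)
  if (length(ic_sweeps) < 1) abort("at least one sweep is required.")
  purrr::walk(ic_sweeps, assert_mode, mode = "IC",
              what = "classify_polarity()")
  lt <- sweep_light(ic_sweeps[[1]])
  if (is.na(lt$onset_s))
    abort("sweeps lack light metadata.", class = "gabashunt_light_error")

  traces <- vapply(ic_sweeps, function(s) s$recorded,
                   numeric(nrow(ic_sweeps[[1]])))
  avg <- rowMeans(traces)
  t_s <- ic_sweeps[[1]]$time_s
  base_sel <- t_s >= lt$onset_s - pre_ms / 1e3 & t_s < lt$onset_s
  dur <- if (is.na(lt$duration_s)) 0 else lt$duration_s
  t0 <- if (after == "offset") lt$onset_s + dur else lt$onset_s
  post_sel <- t_s >= t0 & t_s < t0 + post_ms / 1e3
  norm <- avg - mean(avg[base_sel])
  m <- mean(norm[post_sel])
  structure(list(mean_post_light_mV = m,
                 label = if (m > 0) "depolarizing" else "hyperpolarizing",
                 n_sweeps = length(ic_sweeps),
                 mean_trace = tibble::tibble(time_s = t_s, vm_norm_mV = norm)),
            class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("<polarity_result> %s (mean post-light deflection %+0.3f mV, %d sweeps)\n",
              x$label, x$mean_post_light_mV, x$n_sweeps))
  invisible(x)
}
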