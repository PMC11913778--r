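#' Select analyzable regular-spiking units
#'
#' Applies the standard unit-selection filters to a sorted-unit session:
#' keep units (i) annotated in the stimulated area (somatosensory
#' annotations `"SSp-ll"`/`"SSp-tr"` when the stimulated area is `"SS"`,
#' secondary motor `"MOs"` when it is `"MO"`), (ii) with spike waveform
#' duration >= 0.4 ms (putative regular-spiking excitatory neurons) and
#' (iii) with an evoked firing rate between 0.1 and 200 Hz in *both*
#' conditions, computed on the evoked window (default 2-12 ms after
#' stimulus onset). The filters commute, so the retained set does not
#' depend on their order.
#'
#' @param session A list with `units` (tibble `unit_id`, `region`,
#'   `waveform_duration_ms`), `rasters` (named list of [spike_raster()]s
#'   with neuron ids matching `unit_id`) and `stim_area` (`"SS"` or
#'   `"MO"`), e.g. from [gen_two_condition_raster()].
#' @param evoked_window_ms Window for the rate filter (ms after stimulus).
#' @param min_wf_ms Waveform-duration threshold (ms).
#' @param rate_bounds_Hz Inclusive evoked-rate bounds applied per condition.
#' @return The `units` tibble restricted to retained units, with per-
#'   condition evoked rates and the individual filter flags attached.
#' @export
select_units <- function(session, evoked_window_ms = c(2, 12),
                         min_wf_ms = 0.4, rate_bounds_Hz = c(0.1, 200)) {
  area_map <- list(SS = c("SSp-ll", "SSp-tr"), MO = "MOs")
  if (!session$stim_area %in% names(area_map))
    abort(sprintf("unknown stimulated-area tag '%s'.", session$stim_area))
  regions <- area_map[[session$stim_area]]

  rates <- purrr::imap(session$rasters, function(r, cond) {
    rr <- evoked_rate(clip_raster(r, evoked_window_ms))
    setNames(rr[, c("neuron", "evoked_rate_Hz")],
             c("unit_id", paste0("rate_", cond, "_Hz")))
  })
  units <- purrr::reduce(rates, dplyr::left_join, by = "unit_id",
                         .init = session$units)
  rate_cols <- grep("^rate_.*_Hz$", names(units), value = TRUE)
  rate_ok <- purrr::reduce(
    purrr::map(rate_cols, function(cl)
      units[[cl]] >= rate_bounds_Hz[1] & units[[cl]] <= rate_bounds_Hz[2]),
    `&`)
  units$pass_region <- units$region %in% regions
  units$pass_waveform <- units$waveform_duration_ms >= min_wf_ms
  units$pass_rate <- rate_ok
  units[units$pass_region & units$pass_waveform & units$pass_rate, ,
        drop = FALSE]
}

#' Paired awake-versus-anesthetized spiking metrics
#'
#' Runs the full paired comparison across sessions: per session, retained
#' units are selected with [select_units()], the per-neuron synchrony,
#' peri-stimulus histogram entropy and evoked rate are computed for each
#' condition on the evoked window (spikes in 2-12 ms after the stimulus,
#' binned over a 0-12 ms 1-ms grid by default), and the paired table is
#' assembled with one row per retained neuron. Paired t-tests on synchrony
#' and entropy and per-session neuron counts are reported.
#'
#' @param sessions A list of sessions (see [select_units()]); sessions
#'   missing one of the two conditions are excluded with a message.
#' @param conditions Names of the two conditions to pair.
#' @param keep_ms Spike-retention window (ms).
#' @param window_ms Histogram window (ms).
#' @param bin_ms Histogram bin (ms).
#' @param include_self Passed to [synchrony_per_neuron()].
#' @return A list of class `paired_metrics`: `table` (one row per retained
#'   neuron with per-condition synchrony/entropy/rate), `tests` (paired
#'   t-tests), `session_counts`, `summary` (mean and SEM per condition).
#' @export
paired_metrics <- function(sessions,
                           conditions = c("awake", "anesthetized"),
                           keep_ms = c(2, 12), window_ms = c(0, 12),
                           bin_ms = 1, include_self = TRUE) {
  if (inherits(sessions, "npx_session")) sessions <- list(sessions)
  rows <- purrr::imap_dfr(sessions, function(ses, sid) {
    if (!all(conditions %in% names(ses$rasters))) {
      rlang::inform(sprintf("session %s lacks a condition; excluded.", sid))
      return(NULL)
    }
    kept <- select_units(ses, evoked_window_ms = keep_ms)
    if (nrow(kept) == 0) return(NULL)
    per_cond <- purrr::map(conditions, function(cond) {
      r <- clip_raster(ses$rasters[[cond]], keep_ms, window = window_ms)
      m <- neuron_metrics(r, bin_ms = bin_ms, include_self = include_self)
      m <- m[m$neuron %in% kept$unit_id, ]
      names(m)[-1] <- paste0(names(m)[-1], "_", cond)
      m
    })
    out <- purrr::reduce(per_cond, dplyr::left_join, by = "neuron")
    out$session <- as.character(sid)
    out
  })
  if (nrow(rows) == 0)
    abort("no retained neurons across sessions.",
          class = "gabashunt_insufficient_data")

  a <- conditions[1]; b <- conditions[2]
  test_of <- function(metric) {
    x <- rows[[paste0(metric, "_", a)]]
    y <- rows[[paste0(metric, "_", b)]]
    ok <- is.finite(x) & is.finite(y)
    tt <- t.test(x[ok], y[ok], paired = TRUE)
    tibble::tibble(metric = metric,
                   mean_diff = unname(tt$estimate),
                   statistic = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value, n = sum(ok))
  }
  sem <- function(v) sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
  summary <- purrr::map_dfr(conditions, function(cond) {
    tibble::tibble(
      condition = cond,
      synchrony_mean = mean(rows[[paste0("synchrony_", cond)]], na.rm = TRUE),
      synchrony_sem = sem(rows[[paste0("synchrony_", cond)]]),
      entropy_mean = mean(rows[[paste0("entropy_nats_", cond)]], na.rm = TRUE),
      entropy_sem = sem(rows[[paste0("entropy_nats_", cond)]]),
      rate_mean_Hz = mean(rows[[paste0("evoked_rate_Hz_", cond)]], na.rm = TRUE))
  })
  structure(list(
    table = rows,
    tests = dplyr::bind_rows(test_of("synchrony"), test_of("entropy_nats")),
    session_counts = dplyr::count(rows, .data$session, name = "n_neurons"),
    summary = summary,
    conditions = conditions),
    class = "paired_metrics")
}

#' @export
print.paired_metrics <- function(x, ...) {
  cat(sprintf("<paired_metrics> %d neurons from %d sessions\n",
              nrow(x$table), nrow(x$session_counts)))
  print(x$summary)
  print(x$tests)
  invisible(x)
}

#' @rdname tidy.egaba_fit
#' @method tidy paired_metrics
#' @export
tidy.paired_metrics <- function(x, ...) x$table

#' @rdname tidy.egaba_fit
#' @method glance paired_metrics
#' @export
glance.paired_metrics <- function(x, ...) {
  tidyr::pivot_wider(x$tests, names_from = "metric",
                     values_from = c("mean_diff", "p_value", "statistic",
                                     "df", "n"))
}
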