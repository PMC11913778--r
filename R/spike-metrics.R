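#' Per-neuron trial-to-trial synchrony
#'
#' Quantifies how closely each neuron's spiking follows the population on a
#' trial-by-trial basis. For every trial the population peri-stimulus
#' histogram (all neurons, `bin_ms` bins over the raster window) is divided
#' by that trial's total spike count, so each bin holds the fraction of the
#' trial's spikes that fell into it. A neuron's synchrony is the mean, over
#' all of its spikes in all trials, of the normalized-histogram value of the
#' bin containing each spike. The measure is bounded in `[0, 1]`: it is 1
#' when every trial's spikes land in a single shared bin and approaches the
#' chance floor when spikes are scattered independently.
#'
#' By default a neuron's own spikes are part of the population histogram it
#' reads from; set `include_self = FALSE` to remove the neuron from its own
#' reference (both counts and trial totals).
#'
#' @param raster A [spike_raster()].
#' @param bin_ms Histogram bin width (ms).
#' @param include_self Include the neuron's own spikes in the population
#'   reference.
#' @return Tibble with one row per neuron (`neuron`, `synchrony`,
#'   `n_spikes`, `defined`); `synchrony` is `NA` and `defined` `FALSE` for
#'   neurons with no spikes in the window.
#' @export
synchrony_per_neuron <- function(raster, bin_ms = 1, include_self = TRUE) {
  if (nrow(raster) == 0)
    abort("empty raster.", class = "gabashunt_insufficient_data")
  win <- raster_window(raster)
  n_bins <- ceiling((win[2] - win[1]) / bin_ms)
  ev <- tibble::as_tibble(raster)
  ev <- ev[ev$t_ms >= win[1] & ev$t_ms < win[2], , drop = FALSE]
  ev$bin <- pmin(n_bins, 1L + floor((ev$t_ms - win[1]) / bin_ms))

  # per (trial, bin) population counts and per-trial totals
  tb <- dplyr::count(ev, .data$trial, .data$bin, name = "count")
  tot <- dplyr::count(ev, .data$trial, name = "total")
  ev <- ev |>
    dplyr::left_join(tb, by = c("trial", "bin")) |>
    dplyr::left_join(tot, by = "trial")
  if (include_self) {
    ev$value <- ev$count / ev$total
  } else {
    own <- dplyr::count(ev, .data$neuron, .data$trial, .data$bin,
                        name = "own_bin")
    own_tot <- dplyr::count(ev, .data$neuron, .data$trial, name = "own_total")
    ev <- ev |>
      dplyr::left_join(own, by = c("neuron", "trial", "bin")) |>
      dplyr::left_join(own_tot, by = c("neuron", "trial"))
    denom <- ev$total - ev$own_total
    ev$value <- ifelse(denom > 0, (ev$count - ev$own_bin) / denom, NA_real_)
  }
  per <- ev |>
    dplyr::group_by(.data$neuron) |>
    dplyr::summarise(synchrony = mean(.data$value, na.rm = TRUE),
                     n_spikes = dplyr::n(), .groups = "drop")
  tibble::tibble(neuron = seq_len(raster_n_neurons(raster))) |>
    dplyr::left_join(per, by = "neuron") |>
    dplyr::mutate(n_spikes = dplyr::coalesce(.data$n_spikes, 0L),
                  defined = !is.na(.data$synchrony))
}

#' Peri-stimulus histogram entropy per neuron
#'
#' For each neuron the peri-stimulus spike histogram over all trials
#' (`bin_ms` bins over the raster window) is normalized to a probability
#' vector `p`, and the entropy `H = -sum(p * log(p))` is computed in nats
#' (zero bins contribute nothing). Low entropy means the neuron's evoked
#' spikes are confined to a few latencies; the maximum is `log(n_bins)` for
#' a uniform histogram.
#'
#' @inheritParams synchrony_per_neuron
#' @return Tibble (`neuron`, `entropy_nats`, `n_spikes`, `defined`);
#'   zero-spike neurons have `NA` entropy.
#' @export
psth_entropy <- function(raster, bin_ms = 1) {
  win <- raster_window(raster)
  n_bins <- ceiling((win[2] - win[1]) / bin_ms)
  ev <- tibble::as_tibble(raster)
  ev <- ev[ev$t_ms >= win[1] & ev$t_ms < win[2], , drop = FALSE]
  ev$bin <- pmin(n_bins, 1L + floor((ev$t_ms - win[1]) / bin_ms))
  per <- ev |>
    dplyr::count(.data$neuron, .data$bin, name = "count") |>
    dplyr::group_by(.data$neuron) |>
    dplyr::summarise(entropy_nats = {
      p <- .data$count / sum(.data$count)
      -sum(p * log(p))
    }, n_spikes = sum(.data$count), .groups = "drop")
  tibble::tibble(neuron = seq_len(raster_n_neurons(raster))) |>
    dplyr::left_join(per, by = "neuron") |>
    dplyr::mutate(n_spikes = dplyr::coalesce(.data$n_spikes, 0L),
                  defined = !is.na(.data$entropy_nats))
}

#' Evoked firing rate per neuron
#'
#' Total spike count in the raster window across trials divided by
#' `n_trials * window length`, in Hz.
#'
#' @inheritParams synchrony_per_neuron
#' @return Tibble (`neuron`, `evoked_rate_Hz`, `n_spikes`).
#' @export
evoked_rate <- function(raster) {
  win <- raster_window(raster)
  win_s <- (win[2] - win[1]) / 1e3
  if (win_s <= 0) abort("raster window has zero length.")
  ev <- tibble::as_tibble(raster)
  ev <- ev[ev$t_ms >= win[1] & ev$t_ms < win[2], , drop = FALSE]
  per <- dplyr::count(ev, .data$neuron, name = "n_spikes")
  tibble::tibble(neuron = seq_len(raster_n_neurons(raster))) |>
    dplyr::left_join(per, by = "neuron") |>
    dplyr::mutate(n_spikes = dplyr::coalesce(.data$n_spikes, 0L),
                  evoked_rate_Hz = .data$n_spikes /
                    (raster_n_trials(raster) * win_s)) |>
    dplyr::select("neuron", "evoked_rate_Hz", "n_spikes")
}

#' All per-neuron raster metrics in one table
#'
#' Convenience wrapper joining [synchrony_per_neuron()], [psth_entropy()]
#' and [evoked_rate()].
#'
#' @inheritParams synchrony_per_neuron
#' @export
neuron_metrics <- function(raster, bin_ms = 1, include_self = TRUE) {
  synchrony_per_neuron(raster, bin_ms, include_self) |>
    dplyr::select("neuron", "synchrony") |>
    dplyr::left_join(dplyr::select(psth_entropy(raster, bin_ms),
                                   "neuron", "entropy_nats"),
                     by = "neuron") |>
    dplyr::left_join(evoked_rate(raster), by = "neuron")
}

#' Regress firing rate out of a metric
#'
#' Tests whether a two-condition difference in a per-neuron metric survives
#' after removing the linear effect of firing rate. The metric is regressed
#' on rate (and, separately, on log rate) by least squares across all rows,
#' residuals are returned, and the paired between-condition test is re-run
#' on the residuals.
#'
#' @param data Data frame with columns `neuron`, `condition` (two levels),
#'   the metric and the rate.
#' @param metric,rate Column names (strings) of the metric and the rate.
#' @return A list of class `rate_regression`: `residuals` (input data plus
#'   `resid_rate`, `resid_lograte`), `fits` (tidy slope/intercept per
#'   model), `paired_tests` (paired t-test on residuals per model).
#' @export
regress_out_rate <- function(data, metric = "synchrony",
                             rate = "evoked_rate_Hz") {
  stopifnot(all(c("neuron", "condition", metric, rate) %in% names(data)))
  if (nrow(data) < 3)
    abort("need at least 3 paired observations.",
          class = "gabashunt_insufficient_data")
  y <- data[[metric]]
  r <- data[[rate]]
  if (sd(r) == 0)
    abort("rates are constant: degenerate fit.",
          class = "gabashunt_degenerate_fit")
  f1 <- lm(y ~ r)
  lr <- log(pmax(r, .Machine$double.eps))
  f2 <- lm(y ~ lr)
  out <- tibble::as_tibble(data)
  out$resid_rate <- residuals(f1)
  out$resid_lograte <- residuals(f2)

  paired_t <- function(col) {
    wide <- tidyr::pivot_wider(out[, c("neuron", "condition", col)],
                               names_from = "condition",
                               values_from = dplyr::all_of(col))
    conds <- setdiff(names(wide), "neuron")
    tt <- t.test(wide[[conds[1]]], wide[[conds[2]]], paired = TRUE)
    tibble::tibble(model = col, estimate = unname(tt$estimate),
                   statistic = unname(tt$statistic),
                   p_value = tt$p.value, df = unname(tt$parameter))
  }
  structure(list(
    residuals = out,
    fits = tibble::tibble(model = c("rate", "log_rate"),
                          slope = c(coef(f1)[[2]], coef(f2)[[2]]),
                          intercept = c(coef(f1)[[1]], coef(f2)[[1]])),
    paired_tests = dplyr::bind_rows(paired_t("resid_rate"),
                                    paired_t("resid_lograte"))),
    class = "rate_regression")
}

#' @export
print.rate_regression <- function(x, ...) {
  cat("<rate_regression>\n")
  print(x$paired_tests)
  invisible(x)
}
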