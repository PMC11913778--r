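#' Construct a stimulus-aligned spike raster
#'
#' A spike raster holds spike times relative to stimulus onset for a
#' population of neurons over repeated trials, as a tidy event table
#' (`neuron`, `trial`, `t_ms`, optionally `pattern`). Neurons and trials
#' with no spikes are still part of the raster via the `n_neurons` /
#' `n_trials` metadata.
#'
#' @param events Data frame with integer columns `neuron`, `trial` and
#'   numeric `t_ms`; an optional `pattern` column labels each trial's
#'   stimulus pattern.
#' @param n_neurons,n_trials Population and trial counts.
#' @param window `c(t0, t1)` analysis window in ms.
#' @param condition Optional condition tag (e.g. `"awake"`, `"shunting"`).
#' @param trial_patterns Optional integer vector of length `n_trials` with
#'   the pattern id of each trial (alternative to a `pattern` column).
#' @return A tibble of class `spike_raster`.
#' @export
spike_raster <- function(events, n_neurons, n_trials, window,
                         condition = NA_character_, trial_patterns = NULL) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("neuron", "trial", "t_ms") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$neuron < 1 | events$neuron > n_neurons))
      abort("neuron ids outside 1..n_neurons.")
    if (any(events$trial < 1 | events$trial > n_trials))
      abort("trial ids outside 1..n_trials.")
  }
  events <- dplyr::arrange(events, .data$neuron, .data$trial, .data$t_ms)
  if (!is.null(trial_patterns)) {
    stopifnot(length(trial_patterns) == n_trials)
    events$pattern <- trial_patterns[events$trial]
  }
  structure(events,
            class = c("spike_raster", class(events)),
            n_neurons = as.integer(n_neurons),
            n_trials = as.integer(n_trials),
            window = as.double(window),
            condition = condition,
            trial_patterns = trial_patterns)
}

#' Raster metadata accessors
#' @param x A `spike_raster`.
#' @export
raster_window <- function(x) attr(x, "window")

#' @rdname raster_window
#' @export
raster_n_neurons <- function(x) attr(x, "n_neurons")

#' @rdname raster_window
#' @export
raster_n_trials <- function(x) attr(x, "n_trials")

#' @rdname raster_window
#' @export
raster_condition <- function(x) attr(x, "condition")

#' Restrict a raster to a time window
#'
#' Keeps only spikes with `t_ms` in `keep` and re-labels the analysis window
#' as `window` (defaults to `keep`). Used, e.g., to retain 2-12 ms spikes
#' while binning over a 0-12 ms histogram grid.
#'
#' @param raster A `spike_raster`.
#' @param keep `c(lo, hi)` in ms; spikes in `[lo, hi)` are retained.
#' @param window New analysis window, defaults to `keep`.
#' @export
clip_raster <- function(raster, keep, window = keep) {
  ev <- raster[raster$t_ms >= keep[1] & raster$t_ms < keep[2], , drop = FALSE]
  spike_raster(tibble::as_tibble(ev), raster_n_neurons(raster),
               raster_n_trials(raster), window,
               condition = raster_condition(raster),
               trial_patterns = attr(raster, "trial_patterns"))
}

#' Read and write rasters as event tables
#'
#' The on-disk dialect is a (optionally gzipped) TSV event table with columns
#' `neuron`, `trial`, `t_ms` and optionally `pattern`, plus a JSON header
#' (`<path>.json`) recording the window, population size, trial count and
#' condition.
#'
#' @param raster A `spike_raster`.
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @export
write_raster_tsv <- function(raster, path) {
  readr::write_tsv(tibble::as_tibble(raster), path, progress = FALSE)
  meta <- list(n_neurons = raster_n_neurons(raster),
               n_trials = raster_n_trials(raster),
               window_ms = raster_window(raster),
               condition = raster_condition(raster))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  cond <- meta$condition
  spike_raster(ev, meta$n_neurons, meta$n_trials,
               as.double(unlist(meta$window_ms)),
               condition = if (is.null(cond)) NA_character_ else cond)
}
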