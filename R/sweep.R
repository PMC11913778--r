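#' Construct a clamp sweep
#'
#' A sweep is one stimulus epoch of patch-clamp data: a regular time base, the
#' command waveform and the recorded signal. In voltage clamp (`mode = "VC"`)
#' the command is in mV and the recorded signal is membrane current in pA; in
#' current clamp (`mode = "IC"`) the command is injected current in pA and the
#' recorded signal is membrane potential in mV. Optogenetic light-pulse
#' metadata ride along as attributes.
#'
#' @param time_s Sample times in seconds (regular grid).
#' @param command Command waveform (mV for VC, pA for IC).
#' @param recorded Recorded signal (pA for VC, mV for IC).
#' @param mode `"VC"` or `"IC"`.
#' @param light_onset_s,light_duration_s Optional light-pulse timing
#'   (seconds), `NA` when no light was delivered.
#' @param sweep_id Label carried through analyses.
#' @return A tibble of class `gs_sweep` with columns `time_s`, `command`,
#'   `recorded` and metadata attributes `mode`, `dt_s`, `light_onset_s`,
#'   `light_duration_s`, `sweep_id`.
#' @examples
#' sw <- sweep_tbl(seq(0, 0.01, by = 1e-4), rep(-70, 101), rnorm(101),
#'                 mode = "VC")
#' sweep_dt(sw)
#' @export
sweep_tbl <- function(time_s, command, recorded, mode = c("VC", "IC"),
                      light_onset_s = NA_real_, light_duration_s = NA_real_,
                      sweep_id = "sweep") {
  mode <- match.arg(mode)
  if (length(command) != length(time_s) || length(recorded) != length(time_s))
    abort("`time_s`, `command` and `recorded` must have the same length.",
          class = "gabashunt_shape_error")
  if (length(time_s) < 2) abort("a sweep needs at least 2 samples.")
  dts <- diff(time_s)
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 1e-6 * dt + 1e-12))
    abort("`time_s` must be a regular, strictly increasing grid.")
  if (!is.na(light_onset_s)) {
    dur <- if (is.na(light_duration_s)) 0 else light_duration_s
    if (light_onset_s < time_s[1] || light_onset_s + dur > time_s[length(time_s)])
      abort("light pulse must fall within the sweep span.")
  }
  out <- tibble::tibble(time_s = as.double(time_s),
                        command = as.double(command),
                        recorded = as.double(recorded))
  structure(out,
            class = c("gs_sweep", class(out)),
            mode = mode, dt_s = dt,
            light_onset_s = light_onset_s,
            light_duration_s = light_duration_s,
            sweep_id = sweep_id)
}

#' Sweep metadata accessors
#'
#' @param x A `gs_sweep`.
#' @return `sweep_dt()` the sample interval in seconds; `sweep_mode()` the
#'   clamp mode; `sweep_light()` a named list with `onset_s` and `duration_s`.
#' @export
sweep_dt <- function(x) attr(x, "dt_s")

#' @rdname sweep_dt
#' @export
sweep_mode <- function(x) attr(x, "mode")

#' @rdname sweep_dt
#' @export
sweep_light <- function(x) {
  list(onset_s = attr(x, "light_onset_s"),
       duration_s = attr(x, "light_duration_s"))
}

assert_mode <- function(sweep, mode, what) {
  if (!inherits(sweep, "gs_sweep"))
    abort(paste0(what, " expects a `gs_sweep` (see `sweep_tbl()`)."))
  if (!identical(sweep_mode(sweep), mode))
    abort(sprintf("%s requires a %s-mode sweep, got %s.", what, mode,
                  sweep_mode(sweep)),
          class = "gabashunt_mode_error")
  invisible(sweep)
}

#' Read and write sweeps in the plain tabular dialect
#'
#' Sweeps are stored as a TSV with columns `time_s`, `command`, `recorded`
#' and a JSON sidecar (`<path>.json`) holding the mode, sample interval,
#' light-pulse metadata and sweep id. This plain-text dialect is what the
#' synthetic generators emit and all analysis functions accept.
#'
#' @param sweep A `gs_sweep`.
#' @param path TSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_sweep_tsv()` returns `path` invisibly; `read_sweep_tsv()`
#'   returns a `gs_sweep`.
#' @export
write_sweep_tsv <- function(sweep, path) {
  stopifnot(inherits(sweep, "gs_sweep"))
  readr::write_tsv(tibble::as_tibble(sweep), path, progress = FALSE)
  meta <- list(mode = sweep_mode(sweep), dt_s = sweep_dt(sweep),
               light_onset_s = attr(sweep, "light_onset_s"),
               light_duration_s = attr(sweep, "light_duration_s"),
               sweep_id = attr(sweep, "sweep_id"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_sweep_tsv
#' @export
read_sweep_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  null_na <- function(x) if (is.null(x)) NA_real_ else as.double(x)
  sweep_tbl(tab$time_s, tab$command, tab$recorded,
            mode = meta$mode,
            light_onset_s = null_na(meta$light_onset_s),
            light_duration_s = null_na(meta$light_duration_s),
            sweep_id = meta$sweep_id %||% "sweep")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
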