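#' Offline series-resistance correction
#'
#' In voltage clamp the access (series) resistance drops part of the command
#' voltage, so the membrane sees `Vm(t) = Vcmd(t) - I(t) * f * Rs`. Online
#' compensation is avoided in vivo because large current fluctuations rupture
#' the perforated patch, so the correction is applied offline: the measured
#' current is multiplied by a fraction (by default 90 %) of the series
#' resistance and the resulting voltage drop is subtracted from the command.
#'
#' Sign convention: currents follow the amplifier convention (inward
#' negative), so a large inward current makes the membrane more depolarized
#' than the command. Worked example: `Vcmd = -70 mV`, `I = -1000 pA`,
#' `Rs = 50 MOhm`, fraction 0.9 gives a drop of
#' `-1000 pA * 0.9 * 50 MOhm = -45 mV` and `Vm = -70 - (-45) = -25 mV`.
#'
#' @param sweep A VC-mode [sweep_tbl()]: command in mV, recorded current in pA.
#' @param rs_MOhm Series resistance in MOhm used for the correction.
#' @param rs_fraction Fraction of `rs_MOhm` corrected for, in `[0, 1]`.
#' @return The input sweep with an added `vm_mV` column, the estimated
#'   membrane potential at each sample.
#' @examples
#' sw <- sweep_tbl(seq(0, 1e-3, 5e-5), rep(-70, 21), rep(-1000, 21), "VC")
#' correct_series_resistance(sw, rs_MOhm = 50)$vm_mV[1]  # -25 mV
#' @export
correct_series_resistance <- function(sweep, rs_MOhm, rs_fraction = 0.9) {
  assert_mode(sweep, "VC", "correct_series_resistance()")
  if (!is.finite(rs_MOhm) || rs_MOhm < 0)
    abort("`rs_MOhm` must be finite and non-negative.")
  if (rs_fraction < 0 || rs_fraction > 1)
    abort("`rs_fraction` must lie in [0, 1].")
  # pA * MOhm = 1e-12 A * 1e6 Ohm = 1e-6 V; convert to mV
  drop_mV <- sweep$recorded * rs_fraction * rs_MOhm * 1e-3
  out <- dplyr::mutate(sweep, vm_mV = .data$command - drop_mV)
  attributes(out)[c("mode", "dt_s", "light_onset_s",
                    "light_duration_s", "sweep_id")] <-
    attributes(sweep)[c("mode", "dt_s", "light_onset_s",
                        "light_duration_s", "sweep_id")]
  class(out) <- class(sweep)
  out
}
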