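#' Voltage-clamp protocol descriptor
#'
#' Describes the ramp and step protocols used to estimate the GABA-A reversal
#' potential. Defaults follow the standard in vivo protocol: hold at -70 mV,
#' 150 ms voltage ramps spanning -130 to -30 mV (nominal rate 0.7 mV/ms) with
#' the first and last 15 ms excluded from fitting to avoid pipette-capacitance
#' transients, and a step grid from -130 to -30 mV in 10 mV increments with
#' 500 ms steps and a 100 ms light pulse delivered 100 ms into each step.
#'
#' @param kind `"ramp"`, `"step"` or `"seal_test"`.
#' @param hold_mV Holding potential (mV).
#' @param ramp_span_mV Length-2 vector, ramp start and end voltage (mV).
#' @param ramp_rate_mV_per_ms Nominal ramp rate used for validation.
#' @param ramp_duration_ms Ramp duration (ms).
#' @param edge_exclusion_ms Portion trimmed from each end of the ramp (ms).
#' @param step_grid_mV Step-protocol command voltages (mV).
#' @param step_duration_ms Step length (ms).
#' @param light_pulse_ms Light-pulse duration (ms): 10 for ramps, 100 for steps.
#' @return A list of class `gs_protocol`.
#' @export
protocol <- function(kind = c("ramp", "step", "seal_test"),
                     hold_mV = -70,
                     ramp_span_mV = c(-130, -30),
                     ramp_rate_mV_per_ms = 0.7,
                     ramp_duration_ms = 150,
                     edge_exclusion_ms = 15,
                     step_grid_mV = seq(-130, -30, by = 10),
                     step_duration_ms = 500,
                     light_pulse_ms = NULL) {
  kind <- match.arg(kind)
  if (is.null(light_pulse_ms))
    light_pulse_ms <- if (kind == "step") 100 else 10
  span <- abs(diff(ramp_span_mV))
  if (ramp_rate_mV_per_ms * ramp_duration_ms < span)
    abort("ramp span is not covered by ramp_rate x ramp_duration.")
  if (edge_exclusion_ms >= ramp_duration_ms / 2)
    abort("edge exclusion must be less than half the ramp duration.")
  structure(list(kind = kind, hold_mV = hold_mV, ramp_span_mV = ramp_span_mV,
                 ramp_rate_mV_per_ms = ramp_rate_mV_per_ms,
                 ramp_duration_ms = ramp_duration_ms,
                 edge_exclusion_ms = edge_exclusion_ms,
                 step_grid_mV = step_grid_mV,
                 step_duration_ms = step_duration_ms,
                 light_pulse_ms = light_pulse_ms),
            class = "gs_protocol")
}
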