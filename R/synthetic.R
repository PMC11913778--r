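#' Ground truth for a synthetic IV session
#'
#' Parameters of the synthetic voltage-clamp cell used by
#' [gen_iv_session()]. Defaults emulate an awake-cortex recording: resting
#' membrane potential -64.2 mV, synaptic GABA-A reversal -63.3 mV, 11.4 nS
#' light-evoked conductance, 50 MOhm series resistance and 50.6 MOhm
#' membrane resistance.
#'
#' @param rmp_mV True resting membrane potential (mV).
#' @param egaba_mV True synaptic GABA-A reversal potential (mV).
#' @param g_gaba_nS Peak light-evoked GABA-A conductance (nS).
#' @param rs_MOhm True series resistance (MOhm).
#' @param rm_MOhm Membrane (leak) resistance (MOhm).
#' @param cm_pF Membrane capacitance (pF), used for seal-test transients.
#' @param noise_pA Gaussian current-noise SD added to recorded traces (pA).
#' @export
iv_truth <- function(rmp_mV = -64.2, egaba_mV = -63.3, g_gaba_nS = 11.4,
                     rs_MOhm = 50, rm_MOhm = 50.6, cm_pF = 100,
                     noise_pA = 10) {
  if (rs_MOhm < 0 || rs_MOhm > 1000)
    abort("`rs_MOhm` must lie in [0, 1000] MOhm.")
  structure(list(rmp_mV = rmp_mV, egaba_mV = egaba_mV,
                 g_gaba_nS = g_gaba_nS, rs_MOhm = rs_MOhm,
                 rm_MOhm = rm_MOhm, cm_pF = cm_pF, noise_pA = noise_pA),
            class = "iv_truth")
}

# Quasi-static voltage-clamp forward model: given the command voltage, the
# leak (1/rm) and synaptic conductances and the true series resistance,
# solve for the membrane potential and the pipette current. This is the
# exact inverse of the offline correction (at fraction 1) for constant
# conductances. Units: mV, nS, pA; rs in MOhm (1/Rs = 1000/rs nS).
iv_forward <- function(v_cmd, g_leak_nS, rmp_mV, g_syn_nS, egaba_mV,
                       rs_MOhm) {
  if (rs_MOhm == 0) {
    vm <- v_cmd
    i <- g_leak_nS * (vm - rmp_mV) + g_syn_nS * (vm - egaba_mV)
  } else {
    g_rs <- 1e3 / rs_MOhm
    vm <- (g_rs * v_cmd + g_leak_nS * rmp_mV + g_syn_nS * egaba_mV) /
      (g_rs + g_leak_nS + g_syn_nS)
    i <- g_rs * (v_cmd - vm)
  }
  list(vm = vm, i_pA = i)
}

#' Generate a complete synthetic IV session
#'
#' Emits every sweep the reversal-potential pipeline consumes, with known
#' ground truth: a seal-test sweep (-10 mV step with the analytic RC
#' transient), baseline and light voltage-ramp sweeps, and a full
#' step-protocol series. Currents are produced by a quasi-static ohmic
#' model with the series-resistance distortion applied forward (the exact
#' inverse of the offline correction) and Gaussian current noise added.
#' Capacitive ramp transients are not modelled; the protocol's edge
#' exclusion removes the samples where they would occur.
#'
#' @param truth An [iv_truth()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @param proto A ramp [protocol()].
#' @param dt_s Sample interval (s); default 5e-5 (20 kHz).
#' @param step_light_tau_ms Alpha time constant of the light-evoked
#'   conductance in the step protocol (peak at this latency; default 20 ms).
#' @param protocols Which protocols to generate (subset of `"seal"`,
#'   `"ramp"`, `"step"`); generating only what a test needs is much faster.
#' @return A list of class `iv_session`: `seal`, `baseline`, `light`
#'   (ramp sweeps), `steps` (list of step sweeps), `ramp_window_s`, `truth`.
#' @export
gen_iv_session <- function(truth = iv_truth(), seed = 1,
                           proto = protocol("ramp"), dt_s = 5e-5,
                           step_light_tau_ms = 20,
                           protocols = c("seal", "ramp", "step")) {
  stopifnot(inherits(truth, "iv_truth"))
  g_leak <- 1e3 / truth$rm_MOhm  # nS
  with_seed(seed, {
    noise <- function(n) {
      if (truth$noise_pA > 0) rnorm(n, 0, truth$noise_pA) else numeric(n)
    }

    seal <- NULL; baseline <- NULL; light <- NULL
    steps <- NULL; ramp_window_s <- NULL
    hold <- proto$hold_mV

    ## --- seal test: -10 mV step, analytic RC response -------------------
    if ("seal" %in% protocols) {
    t_seal <- seq(0, 0.3 - dt_s, by = dt_s)
    cmd <- rep(hold, length(t_seal))
    on_s <- 0.1; off_s <- 0.25
    in_step <- t_seal >= on_s & t_seal < off_s
    cmd[in_step] <- hold - 10
    i_hold <- 1e3 * (hold - truth$rmp_mV) / (truth$rs_MOhm + truth$rm_MOhm)
    i_seal <- rep(i_hold, length(t_seal))
    if (truth$rs_MOhm > 0) {
      tau_ms <- truth$cm_pF * truth$rs_MOhm * truth$rm_MOhm /
        (truth$rs_MOhm + truth$rm_MOhm) * 1e-3
      rc_step <- function(t_rel_ms, dv) {
        ss <- dv / (truth$rs_MOhm + truth$rm_MOhm)
        pk <- dv / truth$rs_MOhm
        1e3 * (ss + (pk - ss) * exp(-t_rel_ms / tau_ms))
      }
      sel_on <- t_seal >= on_s & t_seal < off_s
      i_seal[sel_on] <- i_hold + rc_step((t_seal[sel_on] - on_s) * 1e3, -10)
      # off response: superposed +10 mV step (on-transient fully decayed);
      # steady parts of the two steps cancel, leaving the +10 transient
      sel_off <- t_seal >= off_s
      i_seal[sel_off] <- i_hold +
        rc_step((t_seal[sel_off] - off_s) * 1e3, 10) -
        1e3 * 10 / (truth$rs_MOhm + truth$rm_MOhm)
    } else {
      i_seal[in_step] <- i_hold - 10e3 / truth$rm_MOhm
    }
    seal <- sweep_tbl(t_seal, cmd, i_seal + noise(length(t_seal)),
                      mode = "VC", sweep_id = "seal_test")
    }

    ## --- ramp sweeps ----------------------------------------------------
    if ("ramp" %in% protocols) {
    pre_ms <- 50; post_ms <- 20
    ramp_ms <- proto$ramp_duration_ms
    n_pre <- round(pre_ms / 1e3 / dt_s)
    n_ramp <- round(ramp_ms / 1e3 / dt_s)
    n_post <- round(post_ms / 1e3 / dt_s)
    t_r <- seq_len(n_pre + n_ramp + n_post) * dt_s
    v_cmd <- c(rep(hold, n_pre),
               proto$ramp_span_mV[1] +
                 (seq_len(n_ramp) / n_ramp) * diff(proto$ramp_span_mV),
               rep(hold, n_post))
    ramp_window_s <- c(n_pre + 1, n_pre + n_ramp) * dt_s

    fb <- iv_forward(v_cmd, g_leak, truth$rmp_mV, 0, truth$egaba_mV,
                     truth$rs_MOhm)
    fl <- iv_forward(v_cmd, g_leak, truth$rmp_mV, truth$g_gaba_nS,
                     truth$egaba_mV, truth$rs_MOhm)
    baseline <- sweep_tbl(t_r, v_cmd, fb$i_pA + noise(length(t_r)),
                          mode = "VC", sweep_id = "ramp_baseline")
    light <- sweep_tbl(t_r, v_cmd, fl$i_pA + noise(length(t_r)),
                       mode = "VC",
                       light_onset_s = ramp_window_s[1],
                       light_duration_s = proto$light_pulse_ms / 1e3,
                       sweep_id = "ramp_light")
    }

    ## --- step protocol ---------------------------------------------------
    if ("step" %in% protocols) {
    sp <- protocol("step", hold_mV = hold)
    step_ms <- sp$step_duration_ms
    light_at_ms <- 100
    n_hold <- round(0.1 / dt_s)
    n_step <- round(step_ms / 1e3 / dt_s)
    t_s <- seq_len(n_hold + n_step + n_hold) * dt_s
    steps <- purrr::map(sp$step_grid_mV, function(v_step) {
      cmd_s <- c(rep(hold, n_hold), rep(v_step, n_step), rep(hold, n_hold))
      onset_s <- n_hold * dt_s + light_at_ms / 1e3
      t_rel_ms <- (t_s - onset_s) * 1e3
      g_t <- alpha_conductance(t_rel_ms, truth$g_gaba_nS, step_light_tau_ms)
      f <- iv_forward(cmd_s, g_leak, truth$rmp_mV, g_t, truth$egaba_mV,
                      truth$rs_MOhm)
      sweep_tbl(t_s, cmd_s, f$i_pA + noise(length(t_s)), mode = "VC",
                light_onset_s = onset_s,
                light_duration_s = sp$light_pulse_ms / 1e3,
                sweep_id = sprintf("step_%d", round(v_step)))
    })
    }

    structure(list(seal = seal, baseline = baseline, light = light,
                   steps = steps, ramp_window_s = ramp_window_s,
                   truth = truth, seed = seed),
              class = "iv_session")
  })
}

#' Generate a synthetic spontaneous membrane-potential trace
#'
#' Emulates a continuous current-clamp recording as a sum of two
#' Ornstein-Uhlenbeck processes: a slow component representing synaptic
#' bombardment envelopes and a fast component calibrated analytically so
#' that the expected winsorized mean |dV/dt| matches `target_dvdt` (for a
#' Gaussian increment, `mean |dV| = sqrt(2/pi) * sd`, so the fast innovation
#' SD is chosen as `target_dvdt * sqrt(pi * dt / 2)` after accounting for
#' the slow component). Condition presets follow the awake /
#' anesthetized / activity-blocked regimes: mean Vm -60.3 / -69.1 /
#' -72.6 mV and mean |dV/dt| 6.6 / 4.9 / 0.7 mV/ms.
#'
#' @param condition `"awake"`, `"anesthetized"` or `"nbqx"`.
#' @param duration_s Trace length (s).
#' @param dt_s Sample interval (s).
#' @param mean_vm_mV,target_dvdt_mV_per_ms Override the condition preset.
#' @param sd_slow_mV,tau_slow_ms,tau_fast_ms Envelope parameters.
#' @param seed Integer seed.
#' @return An IC [sweep_tbl()]; ground truth in attribute `truth`.
#' @export
gen_vm_trace <- function(condition = c("awake", "anesthetized", "nbqx"),
                         duration_s = 20, dt_s = 5e-5,
                         mean_vm_mV = NULL, target_dvdt_mV_per_ms = NULL,
                         sd_slow_mV = 3, tau_slow_ms = 100, tau_fast_ms = 2,
                         seed = 1) {
  condition <- match.arg(condition)
  presets <- list(awake = c(-60.3, 6.6), anesthetized = c(-69.1, 4.9),
                  nbqx = c(-72.6, 0.7))
  mu <- mean_vm_mV %||% presets[[condition]][1]
  target <- target_dvdt_mV_per_ms %||% presets[[condition]][2]
  dt_ms <- dt_s * 1e3

  # mean |dV/dt| of a noise-dominated OU sampled at dt is
  # sqrt(2/pi) * s / sqrt(dt), so the innovation scale follows directly
  s_tot <- target * sqrt(pi * dt_ms / 2)  # mV per sqrt(ms)
  s_slow <- sd_slow_mV * sqrt(2 / tau_slow_ms)
  if (s_slow >= s_tot) s_slow <- 0.5 * s_tot
  s_fast <- sqrt(s_tot^2 - s_slow^2)

  n <- round(duration_s / dt_s)
  ou <- function(s, tau) {
    a <- exp(-dt_ms / tau)
    sd_eq <- s * sqrt(tau / 2)
    x <- numeric(n)
    z <- rnorm(n)
    x[1] <- sd_eq * z[1]
    sig <- sd_eq * sqrt(1 - a^2)
    for (k in 2:n) x[k] <- a * x[k - 1] + sig * z[k]
    x
  }
  vm <- with_seed(seed, mu + ou(s_slow, tau_slow_ms) + ou(s_fast, tau_fast_ms))
  tr <- sweep_tbl(seq_len(n) * dt_s, rep(0, n), vm, mode = "IC",
                  sweep_id = paste0("vm_", condition))
  attr(tr, "truth") <- list(condition = condition, mean_vm_mV = mu,
                            target_dvdt_mV_per_ms = target, seed = seed)
  tr
}

#' Generate light-evoked current-clamp sweeps for polarity analysis
#'
#' One-second sweeps with a 10 ms light pulse; the postsynaptic response is
#' a double-exponential deflection of known peak amplitude plus Gaussian
#' noise.
#'
#' @param n_sweeps Number of sweeps (default 15).
#' @param peak_mV Peak deflection (mV); negative = hyperpolarizing truth.
#' @param noise_sd_mV Per-sample noise SD (mV).
#' @param rmp_mV Baseline membrane potential.
#' @param light_onset_s,light_duration_s Light timing.
#' @param tau_rise_ms,tau_decay_ms Response kinetics.
#' @param dt_s Sample interval.
#' @param seed Integer seed.
#' @return List of IC sweeps.
#' @export
gen_polarity_sweeps <- function(n_sweeps = 15, peak_mV = -2,
                                noise_sd_mV = 0.5, rmp_mV = -65,
                                light_onset_s = 0.4, light_duration_s = 0.01,
                                tau_rise_ms = 5, tau_decay_ms = 50,
                                dt_s = 5e-4, seed = 1) {
  t_s <- seq(0, 1 - dt_s, by = dt_s)
  t_rel <- (t_s - light_onset_s) * 1e3
  shape <- ifelse(t_rel <= 0, 0,
                  exp(-t_rel / tau_decay_ms) - exp(-t_rel / tau_rise_ms))
  shape <- shape / max(shape)
  with_seed(seed, purrr::map(seq_len(n_sweeps), function(k) {
    vm <- rmp_mV + peak_mV * shape + rnorm(length(t_s), 0, noise_sd_mV)
    sweep_tbl(t_s, rep(0, length(t_s)), vm, mode = "IC",
              light_onset_s = light_onset_s,
              light_duration_s = light_duration_s,
              sweep_id = sprintf("polarity_%02d", k))
  }))
}

#' Ground truth for a synthetic two-condition raster
#'
#' Knobs of the shared-event raster generator: per condition, a background
#' firing rate and a shared-event probability `q` that directly controls
#' population synchrony. Defaults emulate the awake (low synchrony, higher
#' rate) versus anesthetized (high synchrony, lower rate) contrast.
#'
#' @param awake,anesthetized Named lists with `base_rate_Hz` and `q`.
#' @param n_neurons,n_trials Raster dimensions.
#' @param window_ms Analysis window `c(t0, t1)` (ms).
#' @param latency_mean_ms,latency_sd_ms Latency profile of the shared event.
#' @export
raster_truth <- function(awake = list(base_rate_Hz = 60, q = 0.3),
                         anesthetized = list(base_rate_Hz = 10, q = 0.6),
                         n_neurons = 60, n_trials = 150,
                         window_ms = c(0, 12),
                         latency_mean_ms = 5, latency_sd_ms = 1.5) {
  stopifnot(awake$q >= 0, awake$q <= 1,
            anesthetized$q >= 0, anesthetized$q <= 1)
  structure(list(awake = awake, anesthetized = anesthetized,
                 n_neurons = n_neurons, n_trials = n_trials,
                 window_ms = window_ms, latency_mean_ms = latency_mean_ms,
                 latency_sd_ms = latency_sd_ms),
            class = "raster_truth")
}

gen_raster_one <- function(base_rate_Hz, q, n_neurons, n_trials, window_ms,
                           latency_mean_ms, latency_sd_ms, condition) {
  t0 <- window_ms[1]; t1 <- window_ms[2]
  win_s <- (t1 - t0) / 1e3
  events <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    ev_t <- min(max(rnorm(1, latency_mean_ms, latency_sd_ms), t0), t1 - 1e-6)
    ev_bin_start <- t0 + floor(ev_t - t0)
    who <- which(runif(n_neurons) < q)
    t_shared <- ev_bin_start + runif(length(who))
    n_bg <- rpois(n_neurons, base_rate_Hz * win_s)
    bg_neuron <- rep(seq_len(n_neurons), n_bg)
    t_bg <- runif(sum(n_bg), t0, t1)
    events[[tr]] <- tibble::tibble(
      neuron = c(who, bg_neuron),
      trial = tr,
      t_ms = c(t_shared, t_bg))
  }
  spike_raster(dplyr::bind_rows(events), n_neurons, n_trials, window_ms,
               condition = condition)
}

#' Generate a synthetic two-condition spike dataset
#'
#' Emulates the statistical structure of paired awake/anesthetized sorted-
#' unit recordings with known ground truth: per trial a latent population
#' event occupies one 1-ms bin (Gaussian latency profile) and every neuron
#' joins it with probability `q`; independent Poisson background spikes are
#' added. Higher `q` yields higher measured synchrony and lower
#' peri-stimulus histogram entropy. Unit metadata (waveform durations and
#' region annotations) are attached so the unit-selection filters are
#' exercised.
#'
#' @param truth A [raster_truth()].
#' @param seed Integer seed.
#' @param p_narrow Fraction of units given a narrow (< 0.4 ms) waveform.
#' @param p_off_region Fraction of units annotated outside the stimulated
#'   area.
#' @param stim_area `"SS"` or `"MO"`.
#' @return A list of class `npx_session`: `units` (tibble `unit_id`,
#'   `region`, `waveform_duration_ms`), `rasters` (named list of rasters),
#'   `stim_area`, `truth`, `seed`.
#' @export
gen_two_condition_raster <- function(truth = raster_truth(), seed = 1,
                                     p_narrow = 0.15, p_off_region = 0.1,
                                     stim_area = "SS") {
  with_seed(seed, {
    rasters <- list(
      awake = gen_raster_one(truth$awake$base_rate_Hz, truth$awake$q,
                             truth$n_neurons, truth$n_trials,
                             truth$window_ms, truth$latency_mean_ms,
                             truth$latency_sd_ms, "awake"),
      anesthetized = gen_raster_one(truth$anesthetized$base_rate_Hz,
                                    truth$anesthetized$q,
                                    truth$n_neurons, truth$n_trials,
                                    truth$window_ms, truth$latency_mean_ms,
                                    truth$latency_sd_ms, "anesthetized"))
    n <- truth$n_neurons
    narrow <- runif(n) < p_narrow
    wf <- ifelse(narrow, runif(n, 0.15, 0.39), runif(n, 0.4, 1.0))
    in_region <- runif(n) >= p_off_region
    region_pool <- if (stim_area == "SS") c("SSp-ll", "SSp-tr") else "MOs"
    off_pool <- if (stim_area == "SS") c("MOs", "VISp") else c("SSp-ll", "VISp")
    region <- ifelse(in_region,
                     sample(region_pool, n, replace = TRUE),
                     sample(off_pool, n, replace = TRUE))
    units <- tibble::tibble(unit_id = seq_len(n), region = region,
                            waveform_duration_ms = wf)
    structure(list(units = units, rasters = rasters, stim_area = stim_area,
                   truth = truth, seed = seed),
              class = "npx_session")
  })
}

#' Generate a ball-and-stick morphology
#'
#' A spherical soma plus a single cylindrical dendrite along +x, attached
#' at the soma surface, with nodes every `seg_len_um`. The analytic surface
#' areas (soma `4 pi r^2`, dendrite `2 pi r L`) are recorded in the
#' `truth` attribute for round-trip checks.
#'
#' @param soma_radius_um Soma radius (um).
#' @param dend_length_um Dendrite length (um); 0 for a soma-only model.
#' @param dend_radius_um Dendrite radius (um). The default (2 um, i.e. a
#'   4 um calibre trunk) matches a proximal pyramidal-cell dendrite, so
#'   perisomatic synapse sites stay electrotonically close to the soma as
#'   they are on a real reconstruction.
#' @param seg_len_um Node spacing along the dendrite (um).
#' @return A `morphology`; attribute `truth` holds the analytic areas.
#' @export
gen_ballstick_swc <- function(soma_radius_um = 8, dend_length_um = 300,
                              dend_radius_um = 2, seg_len_um = 10) {
  stopifnot(soma_radius_um > 0, dend_length_um >= 0)
  rows <- list(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                          radius_um = soma_radius_um, parent = -1))
  if (dend_length_um > 0) {
    xs <- seq(seg_len_um, dend_length_um, by = seg_len_um)
    if (utils::tail(xs, 1) < dend_length_um) xs <- c(xs, dend_length_um)
    xs <- xs + soma_radius_um
    ids <- seq_along(xs) + 1
    rows[[2]] <- data.frame(id = ids, type = 3, x = xs, y = 0, z = 0,
                            radius_um = dend_radius_um,
                            parent = c(1, ids[-length(ids)]))
  }
  m <- as_morphology(dplyr::bind_rows(rows))
  attr(m, "truth") <- list(
    soma_area_cm2 = 4 * pi * (soma_radius_um * 1e-4)^2,
    dend_area_cm2 = 2 * pi * (dend_radius_um * 1e-4) * (dend_length_um * 1e-4),
    soma_radius_um = soma_radius_um, dend_length_um = dend_length_um,
    dend_radius_um = dend_radius_um)
  m
}

#' Passive length constant of a cylindrical cable
#'
#' `lambda = sqrt(r_m * a / (2 * r_axial))` for radius `a`, in um.
#'
#' @param params A [passive_params()].
#' @param radius_um Cable radius (um).
#' @export
cable_length_constant_um <- function(params, radius_um) {
  a_cm <- radius_um * 1e-4
  sqrt(params$r_m_Ohm_cm2 * a_cm / (2 * params$r_axial_Ohm_cm)) * 1e4
}
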