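#' Configuration of the recurrent E/I integrate-and-fire network
#'
#' Parameters of the 800-excitatory / 200-inhibitory conductance-based
#' leaky integrate-and-fire network used to contrast shunting and
#' hyperpolarizing synaptic inhibition. Defaults follow the reference
#' parameter set: leak reversal (equivalent to RMP) -60 mV, glutamatergic
#' reversal 0 mV, excitatory/inhibitory conductance decay 5/10 ms, membrane
#' capacitance 200 pF, membrane time constant 5 ms (so the leak conductance
#' is `c_m / tau_m = 40 nS`), refractory period 5 ms, uniform 10 %
#' connection probability, 0.1 nS glutamatergic weights and 1 nS initial
#' GABAergic weights. The GABA-A reversal in the inhibitory population is
#' fixed at -60 mV; in the pyramidal population it is the experimental
#' contrast: -60 mV (shunting) or -80 mV (hyperpolarizing). Spike threshold
#' and reset are not part of the reference set; the defaults (-50 mV
#' threshold, reset at the leak reversal) give a 10 mV leak-to-threshold
#' span.
#'
#' @param n_exc,n_inh Population sizes.
#' @param p_conn Connection probability per ordered pair (no
#'   self-connections).
#' @param w_exc Glutamatergic synaptic weight (nS).
#' @param w_inh_init Initial GABAergic weight before balancing (nS).
#' @param e_leak,e_glut,egaba_inh Reversal potentials (mV).
#' @param tau_exc_syn,tau_inh_syn Synaptic conductance decay constants (ms).
#' @param c_m Membrane capacitance (pF).
#' @param tau_m Membrane time constant (ms).
#' @param t_refractory Refractory period (ms).
#' @param v_threshold,v_reset Spike threshold and reset (mV).
#' @param syn_delay Monosynaptic transmission delay (ms).
#' @param dt Integration step (ms).
#' @return A list of class `network_config`.
#' @export
network_config <- function(n_exc = 800, n_inh = 200, p_conn = 0.10,
                           w_exc = 0.1, w_inh_init = 1,
                           e_leak = -60, e_glut = 0, egaba_inh = -60,
                           tau_exc_syn = 5, tau_inh_syn = 10,
                           c_m = 200, tau_m = 5, t_refractory = 5,
                           v_threshold = -50, v_reset = e_leak,
                           syn_delay = 1.5, dt = 0.1) {
  if (p_conn < 0 || p_conn > 1) abort("`p_conn` must lie in [0, 1].")
  if (any(c(tau_exc_syn, tau_inh_syn, tau_m, dt) <= 0))
    abort("time constants and dt must be positive.")
  cfg <- list(n_exc = n_exc, n_inh = n_inh, p_conn = p_conn, w_exc = w_exc,
              w_inh_init = w_inh_init, e_leak = e_leak, e_glut = e_glut,
              egaba_inh = egaba_inh, tau_exc_syn = tau_exc_syn,
              tau_inh_syn = tau_inh_syn, c_m = c_m, tau_m = tau_m,
              t_refractory = t_refractory, v_threshold = v_threshold,
              v_reset = v_reset, syn_delay = syn_delay, dt = dt,
              g_leak = c_m / tau_m)
  stopifnot(isTRUE(all.equal(cfg$g_leak, c_m / tau_m)))
  structure(cfg, class = "network_config")
}

#' External input specification
#'
#' Stimulus and noise drive for the network. All amplitudes are drawn from
#' log-normal distributions `X = M * exp(mu + sigma * Z)` with `Z` standard
#' normal, so they are always positive (depolarizing). A stimulus pattern is
#' a set of per-neuron amplitudes delivered as a simultaneous 1 ms pulse,
#' followed by a 25 ms pause; every neuron additionally receives an
#' independent noise current whose amplitude is refreshed every 10 ms.
#'
#' @param m_stim Stimulus scale M (pA).
#' @param m_noise Noise scale M (pA).
#' @param mu,sigma Log-normal location and shape.
#' @param pulse_ms,pause_ms Pulse and pause durations (ms).
#' @param noise_refresh_ms Noise refresh interval (ms).
#' @param n_patterns Number of distinct stimulus patterns.
#' @param n_repeats Presentations of each pattern per condition.
#' @export
input_spec <- function(m_stim = 500, m_noise = 25, mu = 0, sigma = 1,
                       pulse_ms = 1, pause_ms = 25, noise_refresh_ms = 10,
                       n_patterns = 100, n_repeats = 100) {
  structure(list(m_stim = m_stim, m_noise = m_noise, mu = mu, sigma = sigma,
                 pulse_ms = pulse_ms, pause_ms = pause_ms,
                 noise_refresh_ms = noise_refresh_ms,
                 n_patterns = n_patterns, n_repeats = n_repeats),
            class = "input_spec")
}

#' Build the random recurrent network
#'
#' Samples directed connectivity Bernoulli(`p_conn`) per ordered pair of
#' neurons (self-connections excluded) and assigns weights by source class:
#' `w_exc` for glutamatergic sources, `w_inh_init` for GABAergic sources.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed; the same seed reproduces the same graph.
#' @return A list of class `lif_network` holding the config, edge lists
#'   (`exc_src`/`exc_tgt`, `inh_src`/`inh_tgt`, 1-based), the inhibitory
#'   weight vector `w_inh`, a `balanced` flag and the seed.
#' @export
build_network <- function(cfg = network_config(), seed = 1) {
  n <- cfg$n_exc + cfg$n_inh
  edges <- with_seed(seed, {
    m <- matrix(runif(n * n) < cfg$p_conn, n, n)  # [src, tgt]
    diag(m) <- FALSE
    which(m, arr.ind = TRUE)
  })
  src <- edges[, 1]
  tgt <- edges[, 2]
  is_exc <- src <= cfg$n_exc
  structure(list(cfg = cfg,
                 exc_src = src[is_exc], exc_tgt = tgt[is_exc],
                 inh_src = src[!is_exc], inh_tgt = tgt[!is_exc],
                 w_inh = rep(cfg$w_inh_init, sum(!is_exc)),
                 balanced = FALSE, seed = seed),
            class = "lif_network")
}

#' @export
print.lif_network <- function(x, ...) {
  cat(sprintf("<lif_network> %dE/%dI, %d exc + %d inh synapses, %s\n",
              x$cfg$n_exc, x$cfg$n_inh, length(x$exc_src), length(x$inh_src),
              if (x$balanced) "balanced (weights frozen)" else "unbalanced"))
  invisible(x)
}

lif_params <- function(cfg, egaba_exc) {
  list(e_leak = cfg$e_leak, e_glut = cfg$e_glut, egaba_exc = egaba_exc,
       egaba_inh = cfg$egaba_inh, tau_exc_syn = cfg$tau_exc_syn,
       tau_inh_syn = cfg$tau_inh_syn, c_m = cfg$c_m, tau_m = cfg$tau_m,
       v_threshold = cfg$v_threshold, v_reset = cfg$v_reset,
       t_refractory = cfg$t_refractory, syn_delay = cfg$syn_delay,
       dt = cfg$dt)
}

make_patterns <- function(n_neurons, inputs, seed) {
  with_seed(seed, matrix(
    inputs$m_stim * exp(inputs$mu + inputs$sigma * rnorm(n_neurons * inputs$n_patterns)),
    nrow = n_neurons, ncol = inputs$n_patterns))
}

#' Balance excitation and inhibition by homeostatic inhibitory plasticity
#'
#' Adapts the GABAergic weights with the symmetric inhibitory
#' spike-timing-dependent plasticity rule (pre spike:
#' `w <- w + eta * (x_post - alpha)`; post spike: `w <- w + eta * x_pre`;
#' `alpha = 2 * rho0 * tau_stdp`), which drives each neuron's firing toward
#' the target rate `rho0` and establishes an excitation/inhibition balance.
#' Balancing runs under the same cyclic pattern + noise input regime used
#' for measurement, with the pyramidal GABA-A reversal at its shunting
#' value; afterwards the weights are frozen.
#'
#' @param network A [build_network()] result.
#' @param inputs An [input_spec()].
#' @param drive Input regime during balancing. `"poisson"` (default):
#'   every neuron receives an independent Poisson train of 1 ms pulses with
#'   log-normal amplitudes (scale `m_stim`), at the same average pulse rate
#'   as the cyclic stimulation (one pulse per cycle); decorrelated drive
#'   keeps the plasticity fixed point at the target rate. `"patterns"`:
#'   the cyclic synchronized pattern stimulation used for measurement
#'   (stimulus-locked correlations bias the achieved rate below target).
#' @param rho0_Hz Target firing rate (Hz).
#' @param eta Learning rate (nS per trace unit).
#' @param tau_stdp_ms Plasticity trace time constant (ms).
#' @param duration_s Simulated balancing time (s).
#' @param egaba_exc GABA-A reversal in pyramidal cells during balancing (mV).
#' @param w_max Weight clip (nS).
#' @param rate_tol Relative tolerance on the final-window mean excitatory
#'   rate; outside `rho0 * (1 +/- rate_tol)` balancing is declared
#'   non-convergent and an error carrying the rate trajectory is raised.
#' @param seed Integer seed.
#' @return The network with adapted, frozen `w_inh`, plus `balance` metadata
#'   (rate trajectory tibble, hyperparameters).
#' @export
balance_inhibition <- function(network, inputs = input_spec(),
                               drive = c("poisson", "patterns"),
                               rho0_Hz = 5, eta = 0.01, tau_stdp_ms = 20,
                               duration_s = 60, egaba_exc = -60,
                               w_max = 100, rate_tol = 0.5, seed = 1) {
  drive <- match.arg(drive)
  cfg <- network$cfg
  n <- cfg$n_exc + cfg$n_inh
  cycle_ms <- inputs$pulse_ms + inputs$pause_ms
  n_cycles <- ceiling(duration_s * 1e3 / cycle_ms)
  patterns <- make_patterns(n, inputs, seed)
  pattern_seq <- with_seed(seed + 1,
    sample.int(inputs$n_patterns, n_cycles, replace = TRUE))
  res <- .lif_simulate_cpp(
    cfg$n_exc, cfg$n_inh,
    network$exc_src - 1L, network$exc_tgt - 1L, cfg$w_exc,
    network$inh_src - 1L, network$inh_tgt - 1L, network$w_inh,
    lif_params(cfg, egaba_exc),
    patterns, pattern_seq,
    inputs$pulse_ms, inputs$pause_ms,
    inputs$m_noise, inputs$mu, inputs$sigma, inputs$noise_refresh_ms,
    TRUE, eta, 2 * (rho0_Hz / 1e3) * tau_stdp_ms, tau_stdp_ms,
    w_max, seed + 2, FALSE,
    drive == "poisson", 1 / (inputs$pulse_ms + inputs$pause_ms),
    inputs$m_stim, inputs$mu, inputs$sigma)

  traj <- tibble::tibble(t_s = seq_along(res$rate_traj_hz),
                         exc_rate_Hz = res$rate_traj_hz)
  whole <- traj[traj$t_s <= floor(duration_s), ]  # drop any partial final bin
  final <- mean(utils::tail(whole$exc_rate_Hz, max(1, round(duration_s / 6))))
  if (eta > 0 &&
      (final < rho0_Hz * (1 - rate_tol) || final > rho0_Hz * (1 + rate_tol))) {
    cnd <- rlang::error_cnd(class = "gabashunt_balance_error",
                            message = sprintf(
      "balancing did not converge: final-window mean excitatory rate %.2f Hz vs target %.2f Hz.",
      final, rho0_Hz), rate_trajectory = traj)
    rlang::cnd_signal(cnd)
  }
  network$w_inh <- res$w_inh
  network$balanced <- TRUE
  network$balance <- list(rate_trajectory = traj, final_rate_Hz = final,
                          drive = drive, rho0_Hz = rho0_Hz, eta = eta,
                          tau_stdp_ms = tau_stdp_ms,
                          duration_s = duration_s, egaba_exc = egaba_exc,
                          seed = seed)
  network
}

#' Simulate the shunting and hyperpolarizing conditions
#'
#' Runs the balanced, frozen network once per condition. Each condition
#' delivers every stimulus pattern `n_repeats` times (patterns interleaved:
#' all patterns in order within each repeat block) with independently
#' refreshed noise; both conditions share the same input sequence so the
#' contrast is paired. Spikes are recorded and returned as stimulus-aligned
#' rasters over the full inter-stimulus cycle.
#'
#' @param network A balanced [lif_network].
#' @param inputs An [input_spec()].
#' @param conditions Named vector of pyramidal GABA-A reversals (mV).
#' @param seed Integer seed (inputs and noise; shared across conditions).
#' @return A list of class `sim_result`: `rasters` (named list of
#'   [spike_raster()]s covering excitatory and inhibitory neurons),
#'   `conditions`, `w_inh` (frozen weights), `inputs`, `seed`.
#' @export
run_conditions <- function(network, inputs = input_spec(),
                           conditions = c(shunting = -60,
                                          hyperpolarizing = -80),
                           seed = 1) {
  if (!network$balanced)
    warn("network has not been balanced; running with initial inhibitory weights.")
  cfg <- network$cfg
  n <- cfg$n_exc + cfg$n_inh
  patterns <- make_patterns(n, inputs, seed * 1000 + 17)
  pattern_seq <- rep(seq_len(inputs$n_patterns), times = inputs$n_repeats)
  cycle_ms <- inputs$pulse_ms + inputs$pause_ms

  rasters <- purrr::imap(conditions, function(egaba, cond_name) {
    res <- .lif_simulate_cpp(
      cfg$n_exc, cfg$n_inh,
      network$exc_src - 1L, network$exc_tgt - 1L, cfg$w_exc,
      network$inh_src - 1L, network$inh_tgt - 1L, network$w_inh,
      lif_params(cfg, egaba),
      patterns, pattern_seq,
      inputs$pulse_ms, inputs$pause_ms,
      inputs$m_noise, inputs$mu, inputs$sigma, inputs$noise_refresh_ms,
      FALSE, 0, 0, 20, 100, seed * 1000 + 29, TRUE,
      FALSE, 0, inputs$m_stim, inputs$mu, inputs$sigma)
    trial <- pmin(length(pattern_seq),
                  1L + as.integer(floor((res$spike_t_ms - 1e-9) / cycle_ms)))
    spike_raster(
      tibble::tibble(neuron = res$spike_neuron, trial = trial,
                     t_ms = res$spike_t_ms - (trial - 1) * cycle_ms),
      n_neurons = n, n_trials = length(pattern_seq),
      window = c(0, cycle_ms), condition = cond_name,
      trial_patterns = pattern_seq)
  })
  structure(list(rasters = rasters, conditions = conditions,
                 w_inh = network$w_inh, inputs = inputs, seed = seed,
                 n_exc = cfg$n_exc),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>\n")
  for (nm in names(x$rasters))
    cat(sprintf("  %-16s E_GABAAR %5.0f mV, %d spikes in %d trials\n", nm,
                x$conditions[[nm]], nrow(x$rasters[[nm]]),
                raster_n_trials(x$rasters[[nm]])))
  invisible(x)
}

#' Restrict a raster to the excitatory population
#'
#' Convenience helper: keeps spikes of neurons `1..n_exc` and relabels the
#' population size, so metrics are computed over pyramidal neurons with the
#' pyramidal population as reference.
#'
#' @param raster A raster produced by [run_conditions()].
#' @param n_exc Number of excitatory neurons.
#' @export
excitatory_raster <- function(raster, n_exc) {
  ev <- raster[raster$neuron <= n_exc, , drop = FALSE]
  spike_raster(tibble::as_tibble(ev), n_exc, raster_n_trials(raster),
               raster_window(raster), condition = raster_condition(raster),
               trial_patterns = attr(raster, "trial_patterns"))
}
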