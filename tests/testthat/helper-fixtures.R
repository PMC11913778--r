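# Small builders shared across test files.

# exact linear IV sweeps: baseline I = g_leak * (V - rmp),
# light I = baseline + g_gaba * (V - egaba); no Rs distortion, no noise
linear_iv_session <- function(rmp = -70, egaba = -60, g_leak = 10,
                              g_gaba = 5) {
  gen_iv_session(iv_truth(rmp_mV = rmp, egaba_mV = egaba,
                          g_gaba_nS = g_gaba, rm_MOhm = 1e3 / g_leak,
                          rs_MOhm = 0, noise_pA = 0),
                 seed = 1, protocols = "ramp")
}

# raster from explicit spike times: list of (neuron, trial, t_ms) rows
raster_from <- function(..., n_neurons, n_trials, window = c(0, 12)) {
  rows <- list(...)
  ev <- tibble::tibble(
    neuron = vapply(rows, `[[`, numeric(1), 1),
    trial = vapply(rows, `[[`, numeric(1), 2),
    t_ms = vapply(rows, `[[`, numeric(1), 3))
  spike_raster(ev, n_neurons, n_trials, window)
}

# tiny balanced network shared by the slower network tests
cached_balanced_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) {
      n <- build_network(network_config(), seed = 1)
      net <<- balance_inhibition(n, input_spec(), duration_s = 60, seed = 1)
    }
    net
  }
})
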