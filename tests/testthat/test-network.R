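test_that("connectivity sampling respects the connection probability", {
  cfg0 <- network_config(n_exc = 8, n_inh = 2, p_conn = 0)
  net0 <- build_network(cfg0, seed = 1)
  expect_equal(length(net0$exc_src) + length(net0$inh_src), 0)

  cfg1 <- network_config(n_exc = 8, n_inh = 2, p_conn = 1)
  net1 <- build_network(cfg1, seed = 1)
  expect_equal(length(net1$exc_src) + length(net1$inh_src), 10 * 9)
  expect_false(any(net1$exc_src == net1$exc_tgt))
  expect_false(any(net1$inh_src == net1$inh_tgt))

  net <- build_network(network_config(), seed = 3)
  n_edges <- length(net$exc_src) + length(net$inh_src)
  n_pairs <- 1000 * 999
  expect_lt(abs(n_edges - n_pairs * 0.1),
            4 * sqrt(n_pairs * 0.1 * 0.9))
})

test_that("the leak conductance is the stated capacitance/time-constant ratio", {
  expect_equal(network_config()$g_leak, 40)
  expect_error(network_config(p_conn = 1.5))
})

test_that("a single neuron under constant suprathreshold current matches the LIF closed form", {
  p <- list(e_leak = -60, e_glut = 0, egaba_exc = -60, egaba_inh = -60,
            tau_exc_syn = 5, tau_inh_syn = 10, c_m = 200, tau_m = 5,
            v_threshold = -50, v_reset = -60, t_refractory = 5,
            syn_delay = 1, dt = 0.01)
  i_const <- 800  # pA
  res <- gabashunt:::.lif_simulate_cpp(
    1L, 0L, integer(0), integer(0), 0.1, integer(0), integer(0), numeric(0),
    p, matrix(i_const, 1, 1), 1L, 1000, 0, 0, 0, 1, 10,
    FALSE, 0, 0, 20, 100, 7, TRUE, FALSE, 0, 500, 0, 1, 0L)
  isi <- unique(round(diff(res$spike_t_ms), 6))
  t_star <- -p$tau_m * log(1 - (p$v_threshold - p$e_leak) *
                             (p$c_m / p$tau_m) / i_const)
  expect_equal(isi, p$t_refractory + t_star, tolerance = 2 * p$dt)
})

test_that("an IPSG at the resting potential is a pure shunt", {
  # neuron 2 (inhibitory) is driven and synapses onto neuron 1 (excitatory,
  # undriven); with E_GABA at rest the recorded Vm of neuron 1 stays put
  p <- list(e_leak = -60, e_glut = 0, egaba_exc = -60, egaba_inh = -60,
            tau_exc_syn = 5, tau_inh_syn = 10, c_m = 200, tau_m = 5,
            v_threshold = -50, v_reset = -60, t_refractory = 5,
            syn_delay = 1, dt = 0.1)
  pat <- matrix(c(0, 3000), 2, 1)  # only the interneuron is driven
  res <- gabashunt:::.lif_simulate_cpp(
    1L, 1L, integer(0), integer(0), 0.1, 1L, 0L, 50,
    p, pat, rep(1L, 20), 1, 25, 0, 0, 1, 10,
    FALSE, 0, 0, 20, 100, 7, TRUE, FALSE, 0, 500, 0, 1, 1L)
  expect_gt(length(res$spike_t_ms), 0)        # the interneuron fired
  expect_lt(max(abs(res$v_trace - p$e_leak)), 0.1)
})

test_that("no input and no noise leaves the network silent", {
  net <- build_network(network_config(n_exc = 40, n_inh = 10), seed = 2)
  inp <- input_spec(m_stim = 0, m_noise = 0, n_patterns = 2, n_repeats = 2)
  net$balanced <- TRUE
  sim <- run_conditions(net, inp, seed = 1)
  expect_equal(nrow(sim$rasters$shunting), 0)
  expect_equal(nrow(sim$rasters$hyperpolarizing), 0)
})

test_that("zero learning rate leaves weights unchanged; balancing freezes them", {
  net <- build_network(network_config(n_exc = 80, n_inh = 20), seed = 4)
  inp <- input_spec(n_patterns = 5, n_repeats = 5)
  frozen <- balance_inhibition(net, inp, eta = 0, duration_s = 2, seed = 1)
  expect_identical(frozen$w_inh, net$w_inh)

  bal <- cached_balanced_net()
  sim <- run_conditions(bal, input_spec(n_patterns = 5, n_repeats = 5),
                        seed = 2)
  expect_identical(sim$w_inh, bal$w_inh)  # bit-identical after freezing
})

test_that("balancing reaches the homeostatic target rate", {
  bal <- cached_balanced_net()
  expect_lt(abs(bal$balance$final_rate_Hz - bal$balance$rho0_Hz),
            0.2 * bal$balance$rho0_Hz)
})

test_that("identical seeds give identical rasters", {
  bal <- cached_balanced_net()
  inp <- input_spec(n_patterns = 5, n_repeats = 5)
  s1 <- run_conditions(bal, inp, seed = 9)
  s2 <- run_conditions(bal, inp, seed = 9)
  expect_identical(tibble::as_tibble(s1$rasters$shunting),
                   tibble::as_tibble(s2$rasters$shunting))
  s3 <- run_conditions(bal, inp, seed = 10)
  expect_false(identical(tibble::as_tibble(s1$rasters$shunting),
                         tibble::as_tibble(s3$rasters$shunting)))
})

test_that("conductances stay non-negative and trials carry pattern labels", {
  bal <- cached_balanced_net()
  expect_true(all(bal$w_inh >= 0))
  sim <- run_conditions(bal, input_spec(n_patterns = 4, n_repeats = 3),
                        seed = 5)
  r <- sim$rasters$shunting
  expect_true(all(r$pattern %in% 1:4))
  expect_true(all(r$t_ms >= 0 & r$t_ms <= 26))
})
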