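test_that("generators are pure functions of their seed", {
  a <- gen_iv_session(seed = 42)
  b <- gen_iv_session(seed = 42)
  expect_identical(a$baseline$recorded, b$baseline$recorded)
  expect_identical(a$seal$recorded, b$seal$recorded)
  expect_identical(a$steps[[3]]$recorded, b$steps[[3]]$recorded)
  expect_false(identical(a$baseline$recorded,
                         gen_iv_session(seed = 43)$baseline$recorded))

  r1 <- gen_two_condition_raster(seed = 8)
  r2 <- gen_two_condition_raster(seed = 8)
  expect_identical(tibble::as_tibble(r1$rasters$awake),
                   tibble::as_tibble(r2$rasters$awake))
  expect_identical(r1$units, r2$units)

  v1 <- gen_vm_trace("awake", duration_s = 11, seed = 5)
  v2 <- gen_vm_trace("awake", duration_s = 11, seed = 5)
  expect_identical(v1$recorded, v2$recorded)
})

test_that("every generator carries a machine-readable ground-truth sidecar", {
  ses <- gen_iv_session(seed = 1, protocols = "ramp")
  expect_s3_class(ses$truth, "iv_truth")
  expect_named(attr(gen_vm_trace(duration_s = 11), "truth"),
               c("condition", "mean_vm_mV", "target_dvdt_mV_per_ms", "seed"))
  expect_s3_class(gen_two_condition_raster(seed = 1)$truth, "raster_truth")
  expect_named(attr(gen_ballstick_swc(), "truth"),
               c("soma_area_cm2", "dend_area_cm2", "soma_radius_um",
                 "dend_length_um", "dend_radius_um"))
})

test_that("forward distortion and offline correction are exact inverses", {
  tr <- iv_truth(rmp_mV = -72, egaba_mV = -68, g_gaba_nS = 9,
                 rs_MOhm = 60, rm_MOhm = 70, noise_pA = 0)
  ses <- gen_iv_session(tr, seed = 2, protocols = "ramp")
  fit <- fit_iv_ramp(ses$baseline, ses$light, rs_MOhm = 60, rs_fraction = 1)
  expect_equal(fit$rmp_mV, -72, tolerance = 1e-8)
  expect_equal(fit$egaba_mV, -68, tolerance = 1e-8)
  expect_equal(fit$g_gaba_nS, 9, tolerance = 1e-8)
})

test_that("raster generator limits: q = 1 and q = 0", {
  # q = 1, no background: everyone spikes in the shared bin
  tr1 <- raster_truth(awake = list(base_rate_Hz = 0, q = 1),
                      n_neurons = 20, n_trials = 40, latency_sd_ms = 0)
  r1 <- gen_two_condition_raster(tr1, seed = 3)$rasters$awake
  m1 <- neuron_metrics(r1)
  expect_true(all(m1$synchrony == 1))
  expect_true(all(m1$entropy_nats == 0))

  # q = 0, high background: near the chance floor / uniform ceiling
  tr0 <- raster_truth(awake = list(base_rate_Hz = 120, q = 0),
                      n_neurons = 30, n_trials = 150)
  r0 <- gen_two_condition_raster(tr0, seed = 3)$rasters$awake
  m0 <- neuron_metrics(r0)
  expect_lt(mean(m0$synchrony), 0.25)
  expect_gt(mean(m0$entropy_nats), 0.85 * log(12))
})

test_that("SWC generator areas agree with read-back computation", {
  m <- gen_ballstick_swc(soma_radius_um = 10, dend_length_um = 120,
                         dend_radius_um = 1.5, seg_len_um = 6)
  tr <- attr(m, "truth")
  expect_equal(m$area_cm2[1], tr$soma_area_cm2)
  expect_equal(sum(m$area_cm2) - m$area_cm2[1], tr$dend_area_cm2,
               tolerance = 1e-10)
})
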