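test_that("SWC parsing computes the stated geometry", {
  soma <- gen_ballstick_swc(soma_radius_um = 6, dend_length_um = 0)
  expect_equal(soma$area_cm2, 4 * pi * (6e-4)^2)

  # two-node cylinder: frustum (here cylinder) lateral area, split between
  # soma-attachment convention and plain nodes
  m <- as_morphology(data.frame(
    id = 1:2, type = c(3, 3), x = c(0, 50), y = 0, z = 0,
    radius_um = c(2, 1), parent = c(-1, 1)))
  slant <- sqrt((50e-4)^2 + (2e-4 - 1e-4)^2)
  expect_equal(sum(m$area_cm2), pi * (2e-4 + 1e-4) * slant)

  tr <- attr(gen_ballstick_swc(), "truth")
  m2 <- gen_ballstick_swc()
  expect_equal(m2$area_cm2[1], tr$soma_area_cm2)
  expect_equal(sum(m2$area_cm2[-1]), tr$dend_area_cm2, tolerance = 1e-9)
})

test_that("malformed SWC data is rejected", {
  base <- data.frame(id = 1:3, type = 3, x = c(0, 10, 20), y = 0, z = 0,
                     radius_um = 1, parent = c(-1, 1, 2))
  bad_radius <- base; bad_radius$radius_um[2] <- 0
  expect_error(as_morphology(bad_radius), "radius")
  orphan <- base; orphan$parent[3] <- 99
  expect_error(as_morphology(orphan), "orphan")
  two_roots <- base; two_roots$parent[2] <- -1
  expect_error(as_morphology(two_roots), "one root")
})

test_that("single-compartment input resistance matches the RC closed form", {
  soma <- gen_ballstick_swc(dend_length_um = 0)
  pp <- passive_params("anesthetized")
  res <- somatic_input_resistance(soma, pp)
  rm_analytic <- pp$r_m_Ohm_cm2 / (4 * pi * (8e-4)^2) / 1e6  # MOhm
  expect_equal(res$rm_MOhm, rm_analytic, tolerance = 0.005)
  expect_equal(res$r_input_MOhm, rm_analytic + pp$clamp_rs_MOhm,
               tolerance = 0.005)

  # doubling the specific membrane resistance doubles Rm (linearity)
  pp2 <- passive_params("anesthetized",
                        r_m_Ohm_cm2 = 2 * pp$r_m_Ohm_cm2)
  expect_equal(somatic_input_resistance(soma, pp2)$rm_MOhm,
               2 * rm_analytic, tolerance = 0.005)
})

test_that("passive linearity: input resistance independent of step sign and size", {
  m <- gen_ballstick_swc()
  pp <- passive_params("awake")
  r1 <- somatic_input_resistance(m, pp, step_mV = -10)$r_input_MOhm
  r2 <- somatic_input_resistance(m, pp, step_mV = +10)$r_input_MOhm
  r3 <- somatic_input_resistance(m, pp, step_mV = -2)$r_input_MOhm
  expect_lt(abs(r2 - r1) / r1, 1e-3)
  expect_lt(abs(r3 - r1) / r1, 1e-3)
})

test_that("with no synaptic input the membrane relaxes to the passive reversal", {
  m <- gen_ballstick_swc()
  pp <- passive_params("nbqx")
  sys <- gabashunt:::cable_system(m, pp)
  v <- gabashunt:::cable_steady_state(sys, pp, v_cmd = pp$e_pas_mV)
  expect_lt(max(abs(v - pp$e_pas_mV)), 1e-6)  # < 1 uV everywhere
})

test_that("the alpha conductance peaks at tau with the stated amplitude", {
  g <- gabashunt:::alpha_conductance(seq(0, 600, 0.5), 2, 150)
  expect_equal(max(g), 2, tolerance = 1e-6)
  expect_equal(seq(0, 600, 0.5)[which.max(g)], 150)
  expect_equal(gabashunt:::alpha_conductance(-5, 2, 150), 0)
})

test_that("the cable length constant follows sqrt(r_m a / (2 r_axial))", {
  pp <- passive_params("awake")
  a_cm <- 1.5e-4
  lam <- sqrt(pp$r_m_Ohm_cm2 * a_cm / (2 * pp$r_axial_Ohm_cm)) * 1e4
  expect_equal(cable_length_constant_um(pp, 1.5), lam)
})

test_that("synapse placement respects the inclusion radius", {
  m <- gen_ballstick_swc()
  pl <- place_synapses(m, n_syn = 20, radius_um = 75, seed = 2)
  expect_length(pl$nodes, 20)
  d <- sqrt((m$x[pl$nodes] - m$x[1])^2)
  expect_true(all(d <= 75))
})

test_that("simulated clamp estimates track the true reversal (awake condition)", {
  m <- gen_ballstick_swc()
  pp <- passive_params("awake")
  pl <- place_synapses(m, seed = 1)
  bc <- run_bias_sweep(m, pp, pl, egaba_grid_mV = c(-85, -65, -45))
  est90 <- bc$egaba_est_mV[bc$correction == 0.9]
  expect_false(is.unsorted(est90))
  b0 <- abs(bc$bias_mV[bc$correction == 0])
  b9 <- abs(bc$bias_mV[bc$correction == 0.9])
  expect_true(all(b9 < b0))
})

test_that("estimates converge under spatial and temporal refinement", {
  m <- gen_ballstick_swc()
  pp <- passive_params("awake")
  pl <- place_synapses(m, seed = 1)
  coarse <- run_bias_sweep(m, pp, pl, egaba_grid_mV = -70,
                           corrections = 0.9)
  m_fine <- refine_morphology(m, 5)
  pl_fine <- place_synapses(m_fine, seed = 1)
  fine <- run_bias_sweep(m_fine, pp, pl_fine, egaba_grid_mV = -70,
                         corrections = 0.9, dt_ms = 0.0125)
  expect_lt(abs(coarse$egaba_est_mV - fine$egaba_est_mV), 0.2)
})

test_that("awake passive constants give lower somatic Rm than activity-blocked", {
  m <- gen_ballstick_swc()
  rm_aw <- somatic_input_resistance(m, passive_params("awake"))$rm_MOhm
  rm_nb <- somatic_input_resistance(m, passive_params("nbqx"))$rm_MOhm
  rm_an <- somatic_input_resistance(m, passive_params("anesthetized"))$rm_MOhm
  expect_lt(rm_aw, rm_an)
  expect_lt(rm_an, rm_nb)
})
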