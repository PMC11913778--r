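test_that("synchrony hand examples", {
  # both neurons spike in the same bin: each reads the full trial mass
  same <- raster_from(c(1, 1, 3.2), c(2, 1, 3.7),
                      n_neurons = 2, n_trials = 1)
  expect_equal(synchrony_per_neuron(same)$synchrony, c(1, 1))
  # different bins: each spike reads half of the trial's spikes
  diff_bins <- raster_from(c(1, 1, 3.2), c(2, 1, 7.7),
                           n_neurons = 2, n_trials = 1)
  expect_equal(synchrony_per_neuron(diff_bins)$synchrony, c(0.5, 0.5))
  # a lone neuron always reads 1 regardless of timing
  lone <- raster_from(c(1, 1, 2.5), c(1, 2, 9.9),
                      n_neurons = 1, n_trials = 2)
  expect_equal(synchrony_per_neuron(lone)$synchrony, 1)
  # exclude-self drops the degenerate upper bound
  es <- synchrony_per_neuron(diff_bins, include_self = FALSE)
  expect_equal(es$synchrony, c(0, 0))
})

test_that("entropy closed forms", {
  # all spikes of a neuron in one bin
  one_bin <- raster_from(c(1, 1, 4.2), c(1, 2, 4.8), c(1, 3, 4.1),
                         n_neurons = 1, n_trials = 3)
  expect_equal(psth_entropy(one_bin)$entropy_nats, 0)
  # uniform over the 12 bins
  uni <- spike_raster(tibble::tibble(neuron = 1, trial = 1:12,
                                     t_ms = (0:11) + 0.5),
                      1, 12, c(0, 12))
  expect_equal(psth_entropy(uni)$entropy_nats, log(12))
  # p = (1/2, 1/2)
  half <- raster_from(c(1, 1, 1.5), c(1, 2, 6.5),
                      n_neurons = 1, n_trials = 2)
  expect_equal(psth_entropy(half)$entropy_nats, log(2))
})

test_that("entropy is invariant to count doubling and neuron relabeling", {
  r <- gen_two_condition_raster(seed = 5)$rasters$awake
  h1 <- psth_entropy(r)
  doubled <- spike_raster(
    dplyr::bind_rows(tibble::as_tibble(r),
                     dplyr::mutate(tibble::as_tibble(r),
                                   trial = .data$trial +
                                     raster_n_trials(r))),
    raster_n_neurons(r), 2L * raster_n_trials(r), raster_window(r))
  expect_equal(psth_entropy(doubled)$entropy_nats, h1$entropy_nats)

  perm <- sample(raster_n_neurons(r))
  relab <- spike_raster(
    dplyr::mutate(tibble::as_tibble(r), neuron = perm[.data$neuron]),
    raster_n_neurons(r), raster_n_trials(r), raster_window(r))
  h2 <- psth_entropy(relab)
  expect_equal(h2$entropy_nats[perm], h1$entropy_nats)
  s1 <- synchrony_per_neuron(r)
  s2 <- synchrony_per_neuron(relab)
  expect_equal(s2$synchrony[perm], s1$synchrony)
})

test_that("metric bounds hold on random rasters", {
  for (sd in 1:5) {
    r <- gen_two_condition_raster(raster_truth(n_neurons = 25, n_trials = 40),
                                  seed = sd)$rasters$anesthetized
    s <- synchrony_per_neuron(r)$synchrony
    h <- psth_entropy(r)$entropy_nats
    expect_true(all(s[!is.na(s)] >= 0 & s[!is.na(s)] <= 1))
    expect_true(all(h[!is.na(h)] <= log(12) + 1e-12))
    expect_true(all(h[!is.na(h)] >= 0))
  }
})

test_that("evoked rate arithmetic and the exclusion threshold", {
  r <- raster_from(c(1, 1, 5), c(1, 10, 6), c(1, 25, 7),
                   n_neurons = 2, n_trials = 30, window = c(2, 12))
  er <- evoked_rate(r)
  expect_equal(er$evoked_rate_Hz, c(3 / (30 * 0.01), 0))  # 10 Hz and 0
  # a 0.05 Hz neuron fails the 0.1 Hz filter bound
  expect_lt(er$evoked_rate_Hz[2], 0.1)
})

test_that("zero-spike neurons are excluded with a flag, empty rasters error", {
  r <- raster_from(c(1, 1, 5), n_neurons = 3, n_trials = 2)
  s <- synchrony_per_neuron(r)
  expect_identical(s$defined, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(s$synchrony[2:3])))
  empty <- spike_raster(tibble::tibble(neuron = integer(), trial = integer(),
                                       t_ms = numeric()), 3, 2, c(0, 12))
  expect_error(synchrony_per_neuron(empty),
               class = "gabashunt_insufficient_data")
})

test_that("measured synchrony rises and entropy falls with the shared-event probability", {
  qs <- seq(0.1, 0.9, by = 0.2)
  res <- purrr::map_dfr(qs, function(q) {
    tr <- raster_truth(awake = list(base_rate_Hz = 30, q = q),
                       n_neurons = 60, n_trials = 250)
    r <- gen_two_condition_raster(tr, seed = 11)$rasters$awake
    m <- neuron_metrics(r)
    tibble::tibble(q = q, sync = mean(m$synchrony, na.rm = TRUE),
                   ent = mean(m$entropy_nats, na.rm = TRUE))
  })
  expect_gt(cor(res$q, res$sync, method = "spearman"), 0.95)
  expect_lt(cor(res$q, res$ent, method = "spearman"), -0.95)
})

test_that("regressing out rate behaves on constructed fixtures", {
  set.seed(1)
  n <- 40
  rate <- runif(2 * n, 1, 20)
  # metric proportional to rate: residuals vanish
  d1 <- tibble::tibble(neuron = rep(1:n, 2),
                       condition = rep(c("a", "b"), each = n),
                       synchrony = 2 * rate, evoked_rate_Hz = rate)
  rr1 <- regress_out_rate(d1)
  expect_lt(max(abs(rr1$residuals$resid_rate)), 1e-10)
  # metric independent of rate: residuals are the centred metric
  met <- rnorm(2 * n)
  d2 <- dplyr::mutate(d1, synchrony = met)
  rr2 <- regress_out_rate(d2)
  expect_equal(cor(rr2$residuals$resid_rate, met), 1, tolerance = 0.02)
  # a genuine condition difference survives residualization
  d3 <- dplyr::mutate(d1, synchrony = 0.1 * rate +
                        ifelse(condition == "a", 0.5, 0) + rnorm(2 * n, 0, 0.1))
  rr3 <- regress_out_rate(d3)
  expect_lt(rr3$paired_tests$p_value[1], 0.01)
  # constant rates are degenerate
  expect_error(regress_out_rate(dplyr::mutate(d1, evoked_rate_Hz = 5)),
               class = "gabashunt_degenerate_fit")
})
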