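test_that("unit-selection filters apply the stated thresholds", {
  ses <- gen_two_condition_raster(seed = 2)
  # force known violations
  ses$units$waveform_duration_ms[1] <- 0.35
  ses$units$region[1:60] <- "SSp-ll"
  kept <- select_units(ses)
  expect_false(1 %in% kept$unit_id)            # narrow waveform excluded
  expect_true(all(kept$waveform_duration_ms >= 0.4))
  expect_true(all(kept$region %in% c("SSp-ll", "SSp-tr")))
  expect_true(all(kept$rate_awake_Hz >= 0.1 & kept$rate_awake_Hz <= 200))
  expect_true(all(kept$rate_anesthetized_Hz >= 0.1 &
                    kept$rate_anesthetized_Hz <= 200))
})

test_that("a rate above 200 Hz in either condition excludes the unit", {
  ses <- gen_two_condition_raster(
    raster_truth(n_neurons = 10, n_trials = 50), seed = 3)
  ses$units$region <- "SSp-ll"
  ses$units$waveform_duration_ms <- 0.6
  # unit 1 fires > 200 Hz in the awake evoked window
  burst <- tidyr::expand_grid(trial = 1:50, t_ms = seq(2.1, 11.9, by = 0.4))
  burst$neuron <- 1L
  aw <- dplyr::bind_rows(tibble::as_tibble(ses$rasters$awake), burst)
  ses$rasters$awake <- spike_raster(aw, 10, 50, c(0, 12),
                                    condition = "awake")
  kept <- select_units(ses)
  expect_false(1 %in% kept$unit_id)
})

test_that("a fully passing synthetic session retains every unit", {
  ses <- gen_two_condition_raster(
    raster_truth(n_neurons = 30, n_trials = 120), seed = 4,
    p_narrow = 0, p_off_region = 0)
  expect_equal(nrow(select_units(ses)), 30)
})

test_that("filters commute: any application order retains the same set", {
  ses <- gen_two_condition_raster(seed = 6)
  full <- select_units(ses)
  # region last instead of first: pre-filter by waveform+rate then region
  ses2 <- ses
  keep_wf <- ses$units$unit_id[ses$units$waveform_duration_ms >= 0.4]
  ses2$units <- ses$units[ses$units$unit_id %in% keep_wf, ]
  partial <- select_units(ses2)
  expect_setequal(full$unit_id, partial$unit_id)
})

test_that("unknown stimulated-area tags are rejected", {
  ses <- gen_two_condition_raster(seed = 1)
  ses$stim_area <- "V1"
  expect_error(select_units(ses), "unknown stimulated-area")
})

test_that("identical spike trains give zero paired differences", {
  ses <- gen_two_condition_raster(seed = 7, p_narrow = 0, p_off_region = 0)
  ses$rasters$anesthetized <- spike_raster(
    tibble::as_tibble(ses$rasters$awake),
    raster_n_neurons(ses$rasters$awake),
    raster_n_trials(ses$rasters$awake),
    raster_window(ses$rasters$awake), condition = "anesthetized")
  pm <- paired_metrics(ses)
  expect_equal(pm$table$synchrony_awake, pm$table$synchrony_anesthetized)
  expect_equal(pm$table$entropy_nats_awake,
               pm$table$entropy_nats_anesthetized)
})

test_that("the paired pipeline recovers the built-in condition contrast", {
  sessions <- purrr::map(1:3, function(sd)
    gen_two_condition_raster(seed = sd))
  pm <- paired_metrics(sessions)
  sm <- pm$summary
  aw <- sm[sm$condition == "awake", ]
  an <- sm[sm$condition == "anesthetized", ]
  expect_lt(aw$synchrony_mean, an$synchrony_mean)
  expect_gt(aw$entropy_mean, an$entropy_mean)
  expect_gt(aw$rate_mean_Hz, an$rate_mean_Hz)
  expect_true(all(pm$tests$p_value < 0.01))
})

test_that("per-session neuron counts are reported (median style)", {
  tr <- function(n) raster_truth(n_neurons = n, n_trials = 60)
  sessions <- purrr::imap(c(3, 1, 9, 3, 4), function(n, i)
    gen_two_condition_raster(tr(n), seed = i,
                             p_narrow = 0, p_off_region = 0))
  pm <- paired_metrics(sessions)
  expect_equal(sort(pm$session_counts$n_neurons), c(1, 3, 3, 4, 9))
  expect_equal(median(pm$session_counts$n_neurons), 3)
})
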