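test_that("perfectly separated one-hot class vectors decode at accuracy 1", {
  n_cls <- 6; reps <- 10
  labels <- rep(seq_len(n_cls), each = reps)
  counts <- matrix(0L, length(labels), n_cls)
  counts[cbind(seq_along(labels), labels)] <- 5L
  res <- decode_patterns(counts, labels, k = 3, seed = 2)
  expect_equal(res$accuracy, 1)
  expect_equal(res$chance, 1 / n_cls)
})

test_that("uninformative vectors decode at chance", {
  set.seed(7)
  n_cls <- 5; reps <- 40
  labels <- rep(seq_len(n_cls), each = reps)
  counts <- matrix(rpois(length(labels) * 20, 3), ncol = 20)  # label-free
  res <- decode_patterns(counts, labels, seed = 3)
  # binomial CI around chance = 0.2 with n = 200
  expect_lt(abs(res$accuracy - res$chance),
            4 * sqrt(0.2 * 0.8 / length(labels)))
})

test_that("label shuffling destroys real structure down to chance", {
  ses <- gen_two_condition_raster(
    raster_truth(n_neurons = 60, n_trials = 100), seed = 9)
  r <- ses$rasters$awake
  # attach synthetic pattern labels that track the event latency so the
  # unshuffled problem is decodable
  ev <- tibble::as_tibble(r)
  med <- tapply(ev$t_ms, ev$trial, stats::median)[as.character(1:100)]
  med[is.na(med)] <- 0
  labels <- as.integer(cut(rank(med, ties.method = "first"), 4))
  pv <- population_vectors(
    spike_raster(ev, 60, 100, c(0, 12), trial_patterns = labels),
    n_sample = 50, seed = 1)
  set.seed(21)
  shuffled <- sample(pv$labels)
  res_sh <- decode_patterns(pv$counts, shuffled, seed = 5)
  expect_lt(abs(res_sh$accuracy - res_sh$chance),
            4 * sqrt(res_sh$chance * (1 - res_sh$chance) / 100) + 0.05)
})

test_that("stratification requires enough members per class", {
  labels <- c(rep(1, 10), rep(2, 3))
  counts <- matrix(0, 13, 4)
  expect_error(decode_patterns(counts, labels, folds = 5),
               class = "gabashunt_stratification_error")
})
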