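test_that("sweep construction validates its invariants", {
  t_s <- seq(0, 0.01, by = 1e-4)
  expect_s3_class(sweep_tbl(t_s, rep(-70, 101), rnorm(101), "VC"), "gs_sweep")
  expect_error(sweep_tbl(t_s, rep(-70, 100), rnorm(101), "VC"),
               class = "gabashunt_shape_error")
  expect_error(sweep_tbl(c(0, 0.1, 0.15), 1:3, 1:3, "VC"),
               "regular")
  expect_error(sweep_tbl(t_s, rep(-70, 101), rnorm(101), "IC",
                         light_onset_s = 0.009, light_duration_s = 0.005),
               "within the sweep span")
})

test_that("sweeps round-trip through the tabular dialect", {
  sw <- sweep_tbl(seq(0, 0.5, by = 5e-4), rep(-70, 1001),
                  rnorm(1001, -50, 5), mode = "IC",
                  light_onset_s = 0.2, light_duration_s = 0.01,
                  sweep_id = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_tsv(sw, path)
  back <- read_sweep_tsv(path)
  expect_equal(back$recorded, sw$recorded)
  expect_equal(sweep_mode(back), "IC")
  expect_equal(sweep_light(back)$onset_s, 0.2)
  expect_equal(attr(back, "sweep_id"), "rt")
})

test_that("rasters round-trip through the event-table dialect", {
  r <- gen_two_condition_raster(seed = 3)$rasters$awake
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  write_raster_tsv(r, path)
  back <- read_raster_tsv(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(r))
  expect_equal(raster_window(back), raster_window(r))
  expect_equal(raster_n_neurons(back), raster_n_neurons(r))
  expect_equal(raster_condition(back), "awake")
})

test_that("morphologies round-trip through SWC text", {
  m <- gen_ballstick_swc()
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  back <- read_swc(path)
  expect_equal(back$radius_um, m$radius_um)
  expect_equal(back$area_cm2, m$area_cm2)
  expect_equal(back$parent, m$parent)
})
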