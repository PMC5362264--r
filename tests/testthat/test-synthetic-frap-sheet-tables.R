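# FRAP-trace, membrane-sheet and measurement-table generators

test_that("noiseless FRAP traces follow the hyperbola exactly", {
  sim <- simulate_frap_trace(frap_spec(true_offset = 0.2, true_recovery = 0.6,
                                       true_t_half = 8, noise_sigma = 0,
                                       seed = 1))
  tr <- sim$trace
  # value at t = 0 is the offset; every sample sits on the hyperbola
  expect_equal(tr$value[tr$time == 0], 0.2)
  expect_equal(tr$value, 0.2 + 0.6 * tr$time / (tr$time + 8))
  # on a 1 Hz grid the sample at t = t_half is exactly offset + M/2
  tr1 <- simulate_frap_trace(frap_spec(frame_rate = 1, duration = 20,
                                       true_offset = 0.2,
                                       true_recovery = 0.6,
                                       true_t_half = 8, noise_sigma = 0,
                                       seed = 1))$trace
  expect_equal(tr1$value[tr1$time == 8], 0.5)
  # 1.2 Hz over 113 s: 136 post-bleach samples (k = 0..135)
  expect_identical(nrow(tr), 136L)
  expect_equal(tr$time, (0:135) / 1.2)
})

test_that("FRAP generator is seed-deterministic and validates its spec", {
  a <- simulate_frap_trace(frap_spec(noise_sigma = 0.05, seed = 3))
  b <- simulate_frap_trace(frap_spec(noise_sigma = 0.05, seed = 3))
  expect_identical(a$trace$value, b$trace$value)
  expect_error(frap_spec(noise_sigma = -0.1, seed = 1), "noise_sigma")
  expect_error(frap_spec(true_t_half = 0, seed = 1), "t_half")
  expect_error(frap_spec(true_offset = 0.6, true_recovery = 0.6, seed = 1),
               "<= 1")
})

test_that("membrane-sheet generator renders density against background", {
  # noiseless: ROI mean minus background is exactly the density
  sh <- simulate_membrane_sheet(sheet_spec(density = 100,
                                           photon_noise = FALSE,
                                           read_noise_sigma = 0, seed = 1))
  m <- measure_sheet_rois(sh$green, sh$blue, data.frame(row = 60, col = 60),
                          background = sh$truth$background_green)
  expect_equal(m$intensity, 100)
  expect_true(m$sheet_ok)
  # zero density: background-subtracted ROI mean ~ 0 under noise
  sh0 <- simulate_membrane_sheet(sheet_spec(density = 0, seed = 2))
  m0 <- measure_sheet_rois(sh0$green, sh0$blue,
                           data.frame(row = 60, col = 60),
                           background = sh0$truth$background_green)
  expect_lt(abs(m0$intensity), 1)
  # doubling density doubles the mean within noise tolerance (same seed)
  d1 <- simulate_membrane_sheet(sheet_spec(density = 200, seed = 7))
  d2 <- simulate_membrane_sheet(sheet_spec(density = 400, seed = 7))
  g <- function(s) measure_sheet_rois(s$green, s$blue,
                                      data.frame(row = 60, col = 60),
                                      background = 20)$intensity
  expect_equal(g(d2) / g(d1), 2, tolerance = 0.05)
  # footprint below the quantification ROI is rejected
  expect_error(sheet_spec(sheet_halfwidth = c(10, 10), seed = 1),
               "30 x 30")
})

test_that("ratio tables reproduce exact ratios at zero CV", {
  tbl <- simulate_ratio_table(
    tibble::tibble(condition = "wt", true_ratio = 2),
    n_replicates = 5, cv = 0, seed = 1)
  r <- membrane_cytosol_ratio(tbl)
  expect_equal(r$ratio, rep(2, 5))
  expect_error(
    simulate_ratio_table(tibble::tibble(condition = "a", true_ratio = 1),
                         cv = -0.1, seed = 1), "cv")
})

test_that("table generators are deterministic and ratio means are unbiased", {
  conds <- tibble::tibble(condition = c("a", "b"), true_ratio = c(1.5, 0.4))
  t1 <- simulate_ratio_table(conds, n_replicates = 1000, cv = 0.1, seed = 9)
  t2 <- simulate_ratio_table(conds, n_replicates = 1000, cv = 0.1, seed = 9)
  expect_identical(t1$intensity, t2$intensity)
  means <- membrane_cytosol_ratio(t1) |>
    dplyr::group_by(condition) |>
    dplyr::summarise(m = mean(ratio))
  expect_equal(means$m[means$condition == "a"], 1.5, tolerance = 0.01)
  expect_equal(means$m[means$condition == "b"], 0.4, tolerance = 0.01)
})

test_that("liposome tables carry matched GST controls with the nonspecific part", {
  design <- tibble::tibble(condition = c("wt", "plus10"),
                           mix = "PIP2",
                           true_specific = c(200, 700),
                           nonspecific = 300)
  tbl <- simulate_liposome_table(design, n_replicates = 4, cv = 0, seed = 1)
  sp <- specific_liposome_binding(tbl)
  expect_equal(sp$specific[sp$condition == "wt"], rep(200, 4))
  expect_equal(sp$specific[sp$condition == "plus10"], rep(700, 4))
  # GST rows equal to bait rows give zero specific binding
  design0 <- tibble::tibble(condition = "wt", mix = "A",
                            true_specific = 0, nonspecific = 500)
  sp0 <- specific_liposome_binding(
    simulate_liposome_table(design0, n_replicates = 3, cv = 0, seed = 1))
  expect_equal(sp0$specific, rep(0, 3))
})

test_that("measurement tables round-trip through tab-delimited text", {
  tbl <- toy_fractionation_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measurement_table(tbl, path)
  back <- read_measurement_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})
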