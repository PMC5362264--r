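# linescan extraction, normalization, alignment, ratio, day summaries

test_that("axis-aligned extraction equals direct slicing with 5-row averaging", {
  set.seed(1)
  img <- matrix(runif(250 * 250, 0, 100), 250, 250)
  anchor <- c(120, 30)
  tr <- extract_linescan(img, anchor, c(0, 1))
  manual <- colMeans(img[118:122, 30:129])
  expect_equal(tr$value, unname(manual))
  # constant image: every sample equals the constant
  trc <- extract_linescan(matrix(7, 150, 150), c(25, 75), c(1, 0))
  expect_equal(trc$value, rep(7, 100))
})

test_that("diagonal extraction matches the closed form on a linear ramp", {
  img <- ramp_image(220, a = 2, b = 3)
  anchor <- c(30.5, 40.25)
  dir <- c(1, 1)
  tr <- extract_linescan(img, anchor, dir)
  expect_equal(tr$value, expected_ramp_linescan(anchor, dir), tolerance = 1e-12)
})

test_that("diagonal extraction matches a supersampled-rotation oracle on a smooth image", {
  # smooth 2-D Gaussian blob; oracle samples a 10x bilinearly upsampled
  # image with nearest-subpixel lookup
  img <- outer(1:160, 1:160, function(r, c) {
    100 * exp(-((r - 80)^2 + (c - 70)^2) / (2 * 25^2))
  })
  anchor <- c(30, 30)
  dir <- c(1, 0.5)
  tr <- extract_linescan(img, anchor, dir)
  up <- 10
  # oracle trace: nearest subpixel of a virtual 10x-upsampled grid
  d <- dir / sqrt(sum(dir^2))
  perp <- c(-d[2], d[1])
  oracle <- vapply(0:99, function(k) {
    mean(vapply(-2:2, function(o) {
      p <- anchor + k * d + o * perp
      # nearest subpixel centre, then bilinear value of the original image
      ps <- round((p - 0.5) * up + 0.5) # subpixel index
      pc <- (ps - 0.5) / up + 0.5       # its coordinate
      r0 <- floor(pc[1]); c0 <- floor(pc[2])
      fr <- pc[1] - r0; fc <- pc[2] - c0
      (1 - fr) * (1 - fc) * img[r0, c0] + fr * (1 - fc) * img[r0 + 1, c0] +
        (1 - fr) * fc * img[r0, c0 + 1] + fr * fc * img[r0 + 1, c0 + 1]
    }, 1.0))
  }, 1.0)
  expect_equal(tr$value, oracle, tolerance = 2e-3)
})

test_that("footprint overrun is rejected with the overhang length", {
  img <- matrix(0, 120, 120)
  expect_error(extract_linescan(img, c(60, 50), c(0, 1)), "exits the image")
})

test_that("normalization subtracts background, scales peak to 1, records peak index", {
  v <- rep(10, 100)
  tr <- memtarget:::linescan_from_values(v)
  n <- normalize_trace(tr, background = 0)
  expect_equal(n$value, rep(1, 100))
  expect_identical(attr(n, "peak_index"), 1L)  # first-occurrence tie-break
  v2 <- rep(20, 100); v2[40] <- 50
  n2 <- normalize_trace(memtarget:::linescan_from_values(v2), background = 10)
  expect_equal(max(n2$value), 1)
  expect_identical(attr(n2, "peak_index"), 40L)
  expect_equal(n2$value[40], (50 - 10) / 40)
  # non-positive peak after subtraction is rejected
  expect_error(normalize_trace(memtarget:::linescan_from_values(rep(5, 100)),
                               background = 10), "not positive")
  # double normalization is rejected
  expect_error(normalize_trace(n2, background = 0), "already normalized")
})

test_that("peak lands within 1 px of the true membrane crossing on synthetic cells", {
  sim <- simulate_equatorial_cell(quiet_cell(0.6, seed = 4))
  r <- cell_ratio(sim)
  expect_lte(abs(r$peak_index - sim$truth$membrane_index), 1)
})

test_that("alignment shifts peaks to a common index and averages with support", {
  v <- rep(0.2, 100); v[30] <- 1
  t1 <- memtarget:::linescan_from_values(v)
  t1 <- normalize_trace(t1, background = 0)
  v2 <- rep(0.2, 100); v2[33] <- 1
  t2 <- normalize_trace(memtarget:::linescan_from_values(v2), background = 0)
  # single trace comes back unchanged over the full index range
  one <- align_and_average(list(t1))
  expect_equal(one$value, t1$value)
  # two identical traces shifted by 3 px: mean equals the unshifted trace
  # over the supported range
  avg <- align_and_average(list(t1, t2))
  common <- avg$index
  shifted_peak <- attr(avg, "peak_index")
  expect_equal(avg$value[avg$index == shifted_peak], 1)
  expect_equal(avg$sd[avg$index == shifted_peak], 0)
  expect_true(all(avg$sd < 1e-12))
  expect_error(align_and_average(list()), "non-empty")
})

test_that("averaging n traces shrinks noise like 1/sqrt(n)", {
  truth <- forward_model_ratio(cell_spec(membrane_fraction = 0.6, seed = 1))
  # per-trace RMSE around the noise-free mean trace vs averaged-trace RMSE
  sims <- lapply(1:20, function(i) {
    simulate_equatorial_cell(cell_spec(membrane_fraction = 0.6,
                                       total_signal = 2e5, seed = 100 + i))
  })
  traces <- lapply(sims, function(s) {
    normalize_trace(extract_linescan(
      s$image, c(s$truth$anchor_row, s$truth$anchor_col), c(0, 1)),
      background = s$truth$background_level,
      search_window = c(21, 41))
  })
  ref <- normalize_trace(extract_linescan(
    simulate_equatorial_cell(quiet_cell(0.6, seed = 1, total_signal = 2e5))$image,
    c(sims[[1]]$truth$anchor_row, sims[[1]]$truth$anchor_col), c(0, 1)),
    background = 10, search_window = c(21, 41))
  avg <- align_and_average(traces)
  common <- intersect(avg$index, ref$index)
  rmse_avg <- sqrt(mean((avg$value[match(common, avg$index)] -
                           ref$value[match(common, ref$index)])^2))
  rmse_single <- sqrt(mean(vapply(traces, function(tr) {
    mean((tr$value[match(common, tr$index)] -
            ref$value[match(common, ref$index)])^2)
  }, 1.0)))
  expect_lt(rmse_avg, rmse_single / sqrt(10))
})

test_that("periphery/cytosol ratio uses the interior window peak+10..peak+14", {
  v <- rep(1, 100)
  tr <- memtarget:::linescan_from_values(v)
  n <- normalize_trace(tr, background = 0)
  expect_equal(periphery_cytosol_ratio(n)$ratio, 1)
  v2 <- rep(0.5, 100); v2[20] <- 1
  n2 <- normalize_trace(memtarget:::linescan_from_values(v2), background = 0)
  r2 <- periphery_cytosol_ratio(n2)
  expect_equal(r2$ratio, 2)
  expect_equal(c(r2$window_start, r2$window_end), c(30, 34))
  # window out of range is rejected
  v3 <- rep(0.5, 100); v3[95] <- 1
  n3 <- normalize_trace(memtarget:::linescan_from_values(v3), background = 0)
  expect_error(periphery_cytosol_ratio(n3), "outside the trace")
})

test_that("annotation files round-trip and are validated", {
  ann <- tibble::tibble(image = "cell1.tif", anchor_row = 150,
                        anchor_col = 80, dir_row = 0, dir_col = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_linescan_annotations(path)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("image\tanchor_row", "a\t1"), bad)
  expect_error(read_linescan_annotations(bad), "lacks column")
})

test_that("condition_summary aggregates cells -> day means -> condition mean/SEM", {
  # days with means {1, 2, 3}: mean 2, SEM = SD/sqrt(3) = 0.5774
  d <- tibble::tibble(day = rep(1:3, each = 2),
                      ratio = c(0.5, 1.5, 2, 2, 2.5, 3.5))
  s <- condition_summary(d, ratio, day)
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-6)
  expect_identical(s$n_days, 3L)
  # single cell, single day: mean defined, SEM flagged NA
  s1 <- condition_summary(tibble::tibble(day = 1, ratio = 1.7), ratio, day)
  expect_equal(s1$mean, 1.7)
  expect_true(is.na(s1$sem))
  # identical day means give SEM 0
  s0 <- condition_summary(tibble::tibble(day = 1:3, ratio = c(2, 2, 2)),
                          ratio, day)
  expect_equal(s0$sem, 0)
})
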