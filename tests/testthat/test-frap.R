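# FRAP normalization, averaging and hyperbolic fitting

test_that("normalization divides background-subtracted post-bleach by pre-bleach mean", {
  frames <- tibble::tibble(time = c(-3, -2, -1, 0, 1) / 1.2,
                           intensity = c(100, 100, 100, 50, 60))
  tr <- normalize_recovery(frames, background = 0, n_prebleach = 3)
  expect_equal(tr$value[1], 0.5)
  expect_equal(tr$time[1], 0)
  # with background: (70 - 20) / (120 - 20) = 0.5
  frames2 <- tibble::tibble(time = c(-3, -2, -1, 0, 2) / 1.2,
                            intensity = c(120, 120, 120, 70, 80))
  tr2 <- normalize_recovery(frames2, background = 20, n_prebleach = 3)
  expect_equal(tr2$value[1], 0.5)
  # pre-bleach not above background is uninterpretable
  expect_error(normalize_recovery(frames2, background = 150), "background")
  expect_error(normalize_recovery(frames, n_prebleach = 2), "pre-bleach")
})

test_that("generator raw frames round-trip through normalize_recovery", {
  sim <- simulate_frap_trace(frap_spec(noise_sigma = 0, seed = 1))
  tr <- normalize_recovery(sim$raw, background = sim$spec$background,
                           n_prebleach = 3)
  expect_equal(tr$value, sim$trace$value, tolerance = 1e-12)
  expect_equal(tr$time, sim$trace$time)
})

test_that("noiseless hyperbola parameters are recovered to ~machine precision", {
  sim <- simulate_frap_trace(frap_spec(true_offset = 0.2, true_recovery = 0.6,
                                       true_t_half = 8, noise_sigma = 0,
                                       seed = 1))
  fit <- fit_hyperbola(sim$trace)
  expect_true(fit$converged)
  expect_equal(fit$offset, 0.2, tolerance = 1e-6)
  expect_equal(fit$recovery, 0.6, tolerance = 1e-6)
  expect_equal(fit$t_half, 8, tolerance = 1e-6)
  # fitted curve passes through offset + M/2 at t = t_half
  expect_equal(predict(fit, tibble::tibble(time = fit$t_half)),
               fit$offset + fit$recovery / 2)
})

test_that("three-point exactly-determined fit matches the closed-form solution", {
  # choose (offset, M, t_half) and three times; the LS solution of the
  # saturated system is the interpolant (residuals 0) -- solve the three
  # equations directly as the oracle
  off <- 0.25; M <- 0.5; th <- 6
  t3 <- c(0, 5, 40)
  y3 <- off + M * t3 / (t3 + th)
  # closed form from the 3 equations: y1 = off;
  # with a = y2 - y1, b = y3 - y1: M and th follow from two saturations
  oracle_off <- y3[1]
  a <- y3[2] - y3[1]; b <- y3[3] - y3[1]
  oracle_th <- t3[2] * t3[3] * (b - a) / (a * t3[3] - b * t3[2])
  oracle_M <- a * (t3[2] + oracle_th) / t3[2]
  # pad with two more exact points to satisfy the n >= 5 contract
  t5 <- c(t3, 12, 20)
  y5 <- off + M * t5 / (t5 + th)
  fit <- fit_hyperbola(tibble::tibble(time = t5, value = y5))
  expect_equal(fit$offset, oracle_off, tolerance = 1e-7)
  expect_equal(fit$recovery, oracle_M, tolerance = 1e-6)
  expect_equal(fit$t_half, oracle_th, tolerance = 1e-6)
})

test_that("time rescaling scales t_half and leaves offset and M unchanged", {
  sim <- simulate_frap_trace(frap_spec(noise_sigma = 0.03, seed = 5))
  fit1 <- fit_hyperbola(sim$trace)
  scaled <- sim$trace
  scaled$time <- scaled$time * 3
  fit3 <- fit_hyperbola(scaled)
  expect_equal(fit3$t_half, 3 * fit1$t_half, tolerance = 1e-5)
  expect_equal(fit3$offset, fit1$offset, tolerance = 1e-6)
  expect_equal(fit3$recovery, fit1$recovery, tolerance = 1e-6)
})

test_that("degenerate traces are rejected or flagged, never silent", {
  flat <- tibble::tibble(time = 0:9, value = rep(0.4, 10))
  expect_error(fit_hyperbola(flat), "unidentifiable")
  expect_error(fit_hyperbola(tibble::tibble(time = 0:3, value = 1:4 / 4)),
               ">= 5")
})

test_that("averaging identical traces gives SD 0, mixed traces the pointwise mean", {
  sim <- simulate_frap_trace(frap_spec(noise_sigma = 0, seed = 1))
  avg <- average_recovery(list(sim$trace, sim$trace))
  expect_equal(avg$sd, rep(0, nrow(avg)))
  t1 <- recovery_trace(0:9, rep(0.4, 10))
  t2 <- recovery_trace(0:9, rep(0.6, 10))
  avg2 <- average_recovery(list(t1, t2))
  expect_equal(avg2$value, rep(0.5, 10))
  # mismatched time bases are rejected
  t3 <- recovery_trace((0:9) / 2, rep(0.5, 10))
  expect_error(average_recovery(list(t1, t3)), "time base")
})

test_that("fitting the averaged trace beats the median single-trace error", {
  sims <- lapply(1:10, function(i) {
    simulate_frap_trace(frap_spec(noise_sigma = 0.05, seed = 200 + i))
  })
  single_err <- vapply(sims, function(s) {
    abs(fit_hyperbola(s$trace)$t_half - 8)
  }, 1.0)
  avg_fit <- fit_hyperbola(average_recovery(lapply(sims, `[[`, "trace")))
  expect_lt(abs(avg_fit$t_half - 8), median(single_err))
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_hyperbola(simulate_frap_trace(frap_spec(noise_sigma = 0.02,
                                                     seed = 3))$trace)
  td <- tidy(fit)
  expect_identical(td$term, c("offset", "recovery", "t_half"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
})
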