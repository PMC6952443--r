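# Baseline estimation: IRLS smoothing, low-rank trend, local correction,
# dF/F0.

test_that("IRLS smoothing preserves constants and linear ramps", {
  expect_lt(max(abs(irls_smooth(rep(3, 50)) - 3)), 1e-9)
  ramp <- seq(0, 10, length.out = 200)
  z <- irls_smooth(ramp)
  expect_lt(max(abs(z - ramp)) / diff(range(ramp)), 0.01)
  expect_error(irls_smooth(c(1, 2, NA, 4, 5, 6)), "finite")
  expect_error(irls_smooth(1:3), "length")
})

test_that("IRLS rejects a boxcar upswing riding on a slow sinusoid", {
  n <- 300
  base <- sin(2 * pi * seq_len(n) / n)
  A <- 2
  y <- base
  y[140:154] <- y[140:154] + A     # boxcar, 5% of trace
  z <- irls_smooth(y)
  expect_lt(max(abs(z - base)), 0.2 * A)
})

test_that("rank-1 matrices with smooth temporal factors are reproduced", {
  # one cycle over 300 frames: well inside the smoother's passband
  u <- 2 + sin(2 * pi * seq_len(300) / 300)
  v <- runif(50, 1, 2)
  M <- outer(u, v)
  Tr <- lowrank_trend(M, r = 1)
  expect_lt(sqrt(mean((Tr - M)^2)) / sqrt(mean(M^2)), 0.05)
  # constant matrix comes back unchanged
  C <- matrix(5, 20, 30)
  expect_equal(lowrank_trend(C, r = 2), C)
  expect_error(lowrank_trend(M, r = 0), "r")
})

test_that("low-rank stage output has numerical rank at most r = 20", {
  sim <- cached_movie()
  bl <- estimate_baseline(sim$movie$functional, r = 20, local = FALSE)
  M <- flatten_stack(bl$F0)
  expect_lte(astroca:::numerical_rank(M), 20)
})

test_that("local correction is exact for zero and constant residuals", {
  sim <- generate_movie(movie_params(height = 32, width = 32, n_frames = 40,
                                     transient_rate = 0, noise_sd = 0,
                                     rigid_shift_amplitude = 0,
                                     nonrigid_amplitude = 0, seed = 6))
  trend <- sim$movie$functional
  out <- local_correction(trend, trend, window_frames = 10, window_px = 8)
  expect_equal(out$F0, trend, tolerance = 1e-10)
  # constant residual c reproduced everywhere: window weights blend to unity
  out2 <- local_correction(trend + 2.5, trend, window_frames = 10,
                           window_px = 8)
  expect_equal(out2$F0, trend + 2.5, tolerance = 1e-8)
  expect_error(local_correction(trend, trend, window_px = 64), "window_px")
})

test_that("local correction lowers the error left by the low-rank trend", {
  sim <- generate_movie(movie_params(height = 64, width = 64, n_frames = 120,
                                     noise_sd = 4, rigid_shift_amplitude = 0,
                                     nonrigid_amplitude = 0, seed = 14))
  # plant a localized slow offset a rank-r global trend cannot represent
  stack <- sim$movie$functional
  bump <- outer(exp(-((1:64 - 16)^2) / 50), exp(-((1:64 - 48)^2) / 50))
  ramp <- seq(0, 1, length.out = 120)
  for (t in 1:120) stack[, , t] <- stack[, , t] + 25 * bump * ramp[t]
  truth <- sim$truth$baseline_movie
  for (t in 1:120) truth[, , t] <- truth[, , t] + 25 * bump * ramp[t]
  bl_trend <- estimate_baseline(stack, r = 4, local = FALSE)
  bl_full <- estimate_baseline(stack, r = 4)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(bl_full$F0, truth), rmse(bl_trend$F0, truth))
})

test_that("dF/F0 definition and floor behave as specified", {
  sim <- generate_movie(movie_params(height = 24, width = 24, n_frames = 20,
                                     transient_rate = 0, noise_sd = 0,
                                     rigid_shift_amplitude = 0,
                                     nonrigid_amplitude = 0, seed = 4))
  F0 <- sim$truth$baseline_movie
  d0 <- compute_dff(sim$movie$functional, F0)
  expect_true(all(d0$dff == 0))
  raised <- sim$movie$functional
  raised[3, 4, 5] <- 1.2 * F0[3, 4, 5]
  d1 <- compute_dff(raised, F0)
  expect_equal(d1$dff[3, 4, 5], 0.2, tolerance = 1e-12)
  # invariant: where F >= 0 and F0 > floor, dff >= -1
  expect_true(all(d1$dff >= -1))
  expect_error(compute_dff(raised, F0, floor = 0), "floor")
})

test_that("dF/F0 peaks on a noiseless movie match planted amplitudes", {
  sim <- generate_movie(movie_params(height = 64, width = 64, n_frames = 200,
                                     noise_sd = 0, rigid_shift_amplitude = 0,
                                     nonrigid_amplitude = 0, seed = 5))
  tr <- sim$truth
  bl <- estimate_baseline(sim$movie$functional)
  dffM <- flatten_stack(compute_dff(sim$movie$functional, bl)$dff)
  for (i in seq_len(max(tr$labels))) {
    s <- tr$roi_traces[, i]
    if (max(s) < 0.3) next
    pk <- which.max(s)
    est <- mean(dffM[pk, which(tr$labels == i)])
    expect_lt(abs(est - s[pk]) / s[pk], 0.02)
  }
})

test_that("F0 stays below transient upswings and inside the raw percentile band", {
  sim <- cached_movie()
  bl <- estimate_baseline(sim$movie$functional)
  tr <- sim$truth
  raw <- flatten_stack(sim$movie$functional)
  f0 <- flatten_stack(bl$F0)
  roi_px <- which(tr$labels > 0)
  set.seed(1); px <- sample(roi_px, 40)
  # under-bias: F0 <= running median + tolerance on >= 95% of samples
  frac_below <- mean(sapply(px, function(j) {
    med <- runmed(raw[, j], 31)
    mean(f0[, j] <= med + 2 * tr$noise_sd)
  }))
  expect_gte(frac_below, 0.95)
  # percentile-band surrogate for visual inspection, referenced against the
  # planted baseline: noise alone keeps even the true F0 below 100% (the
  # 60th sample percentile sits only ~0.25 sd above the mean), so the
  # estimate is held to the oracle's own band fraction minus a margin
  f0_true <- flatten_stack(tr$baseline_movie)
  frac_est <- baseline_band_check(raw[, px], f0[, px], window = 31)
  frac_true <- baseline_band_check(raw[, px], f0_true[, px], window = 31)
  expect_gte(frac_est, frac_true - 0.15)
  expect_gte(frac_est, 0.75)
})
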