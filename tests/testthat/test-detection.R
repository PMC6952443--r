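# Selective averaging and transient detection.

test_that("noise SD estimator is robust to transients and slow trends", {
  expect_equal(estimate_noise_sd(rep(0, 100)), 0)
  expect_equal(estimate_noise_sd(rep(5, 100)), 0)
  set.seed(2)
  x <- rnorm(1000, 0, 0.1)
  est <- estimate_noise_sd(x)
  expect_gt(est, 0.09); expect_lt(est, 0.11)
  expect_lt(abs(est - sd(x)) / sd(x), 0.1)
  xs <- x + 0.5 * sin(seq(0, 6 * pi, length.out = 1000))   # 5x sd slow trend
  expect_lt(abs(estimate_noise_sd(xs) - 0.1) / 0.1, 0.15)
})

test_that("windows of identical traces average to that trace with equal weights", {
  tr <- sin(seq(0, 4 * pi, length.out = 50))
  patch <- matrix(rep(tr, each = 20), 20, 50)
  expect_warning(res <- denoise_window(patch), "distinct")
  expect_equal(res$trace, tr)
  expect_true(all(res$weights == res$weights[1]))
  expect_equal(res$members, 1:20)
})

test_that("center cluster isolates signal-sharing pixels in a labeled patch", {
  set.seed(31)
  nt <- 200
  template <- numeric(nt)
  for (on in c(30, 90, 150))
    template <- template + astroca:::transient_kernel((seq_len(nt) - on),
                                                      1, 4)
  patch <- matrix(rnorm(64 * nt, 0, 0.1), 64, nt)
  patch[1:32, ] <- patch[1:32, ] + rep(0.5 * template, each = 32)
  res <- denoise_window(patch, detection_params())   # center row 32 is signal
  expect_gt(cor(res$trace, template), 0.95)
  expect_true(all(res$members <= 32))   # flat pixels excluded
})

test_that("pure-noise cluster averages shrink noise like the sample mean", {
  set.seed(8)
  agg <- replicate(20, {
    patch <- matrix(rnorm(64 * 300, 0, 0.2), 64, 300)
    res <- denoise_window(patch)
    c(sd(res$trace), length(res$members))
  })
  expected <- 0.2 / sqrt(agg[2, ])
  expect_lt(abs(mean(agg[1, ] / expected) - 1), 0.3)
})

test_that("thresholding finds planted transients and nothing on flat traces", {
  expect_false(any(detect_transients(rep(0, 200), 0.1)))
  trace <- rep(0, 200); trace[60:69] <- 0.5    # amplitude 5 x sd, width 10
  act <- detect_transients(trace, 0.1)
  inter <- sum(act[60:69]); union <- sum(act | (seq_len(200) %in% 60:69))
  expect_gte(inter / union, 0.8)
})

test_that("raising the threshold never increases active frames", {
  set.seed(10)
  trace <- rnorm(500) + c(rep(0, 200), rep(3, 20), rep(0, 280))
  n_active <- sapply(c(1, 2, 3, 4), function(th)
    sum(detect_transients(trace, 1, detection_params(threshold_sd = th))))
  expect_true(all(diff(n_active) <= 0))
})

test_that("pure-noise activity matches the Monte-Carlo null of the same rule", {
  # visible exceedance rate: threshold at 1 SD with no detrending
  prm <- detection_params(threshold_sd = 1, detrend_window = 0)
  sim_fracs <- function(seed, n_traces, known_sd) {
    astroca:::with_seed(seed, {
      vapply(seq_len(n_traces), function(i) {
        x <- rnorm(1000)
        ns <- if (known_sd) 1 else estimate_noise_sd(x)
        mean(detect_transients(x, ns, prm))
      }, numeric(1))
    })
  }
  null_f <- sim_fracs(101, 150, known_sd = TRUE)    # the null oracle
  obs_f <- sim_fracs(202, 150, known_sd = FALSE)    # the estimator's rule
  se <- sqrt(var(null_f) / 150 + var(obs_f) / 150)
  expect_lt(abs(mean(obs_f) - mean(null_f)), 1.96 * se + 1e-3)
  # the default smoothed 2-SD rule is near-silent on pure noise
  expect_lt(null_active_fraction(n_frames = 500, n_reps = 50), 1e-3)
})

test_that("movie-level aggregation is deterministic and exact on shared traces", {
  sim <- generate_movie(movie_params(height = 32, width = 32, n_frames = 60,
                                     noise_sd = 3, seed = 12,
                                     rigid_shift_amplitude = 0,
                                     nonrigid_amplitude = 0))
  dff <- compute_dff(sim$movie$functional, sim$truth$baseline_movie)
  d1 <- selective_average_movie(dff)
  d2 <- selective_average_movie(dff)
  expect_identical(d1$denoised, d2$denoised)
  expect_true(all(d1$weight_sum > 0))
  expect_error(selective_average_movie(dff,
                                       detection_params(window_size = 64)),
               "window_size")
  # all pixels share one trace -> aggregation (a convex combination of
  # whole-window means) returns exactly that trace everywhere
  tr <- sin(seq(0, 6 * pi, length.out = 60))
  shared <- array(rep(tr, each = 32 * 32), c(32, 32, 60))
  ds <- selective_average_movie(shared)
  expect_equal(ds$denoised[5, 9, ], tr, tolerance = 1e-10)
  # window grid symmetry: uniform weight_sum away from the borders
  ws <- ds$weight_sum[9:24, 9:24]
  expect_true(all(ws == ws[1, 1]))
})

test_that("denoising does not amplify noise relative to the planted signal", {
  sim <- generate_movie(movie_params(height = 64, width = 64, n_frames = 300,
                                     noise_sd = 5, seed = 15,
                                     rigid_shift_amplitude = 0,
                                     nonrigid_amplitude = 0))
  tr <- sim$truth
  dff <- compute_dff(sim$movie$functional, tr$baseline_movie)
  den <- selective_average_movie(dff)
  # clean dff signal: transient trace of the pixel's ROI (0 for background)
  clean <- array(0, dim(dff$dff))
  M <- flatten_stack(clean)
  roi_px <- which(tr$labels > 0)
  M[, roi_px] <- tr$roi_traces[, tr$labels[roi_px]]
  denM <- flatten_stack(den$denoised)
  rawM <- flatten_stack(dff$dff)
  resid_den <- sd(denM[, roi_px] - M[, roi_px])
  resid_raw <- sd(rawM[, roi_px] - M[, roi_px])
  expect_lt(resid_den, resid_raw)
})
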