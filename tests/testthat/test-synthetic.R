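# Synthetic data generator: validation, degenerate cases, determinism,
# and internal consistency of the recorded ground truth.

test_that("invalid movie parameters are rejected with the field name", {
  expect_error(movie_params(n_frames = 1), "n_frames")
  expect_error(movie_params(frame_interval = 0), "frame_interval")
  expect_error(movie_params(rise_tau = -1), "rise_tau")
  expect_error(movie_params(noise_sd = -2), "noise_sd")
  expect_error(movie_params(n_somas = -1), "n_somas")
  expect_error(movie_params(height = 16, width = 16, n_frames = 10,
                            drift_rank = 400), "drift_rank")
})

test_that("degenerate generator returns the baseline movie exactly", {
  p <- movie_params(height = 48, width = 48, n_frames = 40,
                    transient_rate = 0, noise_sd = 0,
                    rigid_shift_amplitude = 0, nonrigid_amplitude = 0,
                    seed = 2)
  sim <- generate_movie(p)
  expect_identical(sim$movie$functional, sim$truth$baseline_movie)
  # conservation: mean preserved to machine precision
  expect_equal(mean(sim$movie$functional), mean(sim$truth$baseline_movie),
               tolerance = 1e-12)
})

test_that("identical seeds give bit-identical movies, different seeds differ", {
  p17a <- generate_movie(movie_params(height = 40, width = 40, n_frames = 25,
                                      seed = 17))
  p17b <- generate_movie(movie_params(height = 40, width = 40, n_frames = 25,
                                      seed = 17))
  p18 <- generate_movie(movie_params(height = 40, width = 40, n_frames = 25,
                                     seed = 18))
  expect_identical(p17a$movie, p17b$movie)
  expect_identical(p17a$truth$rigid_shifts, p17b$truth$rigid_shifts)
  expect_false(identical(p17a$movie, p18$movie))
})

test_that("planted active time agrees with the recorded intervals", {
  sim <- cached_movie()
  tr <- sim$truth
  nt <- tr$params$n_frames
  for (i in seq_along(tr$transient_intervals)) {
    iv <- tr$transient_intervals[[i]]
    covered <- sum(pmin(iv[, 2], nt + 1L) - iv[, 1])
    expect_equal(tr$planted_active_time[i], 100 * covered / nt)
    expect_true(tr$planted_active_time[i] >= 0 &&
                  tr$planted_active_time[i] <= 100)
  }
})

test_that("ROI masks are disjoint contiguous regions with recorded classes", {
  sim <- cached_movie()
  lab <- sim$truth$labels
  expect_gt(max(lab), 0)
  expect_equal(length(sim$truth$classes), max(lab))
  for (i in seq_len(max(lab))) {
    cc <- astroca:::label_components(lab == i, 8)
    expect_equal(max(cc), 1)   # contiguous
  }
  # disjoint by construction of a single label image; classes valid
  expect_true(all(sim$truth$classes %in% c("soma", "process", "endfoot")))
})

test_that("generator RNG state does not leak into the session", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_movie(movie_params(height = 32, width = 32,
                                        n_frames = 10, seed = 5)))
  expect_identical(before, .Random.seed)
})

test_that("noiseless physio recordings honor the planted values exactly", {
  p <- physio_params(icp_step = 12, pressor_amplitude = 0, hr_delta = 0,
                     icp_noise_sd = 0, abp_noise_sd = 0,
                     rsna_carrier_sd = 0, response_delay = 30, seed = 3)
  sim <- generate_physio(p)
  expect_equal(max(sim$recording$icp) - p$icp_baseline, 12)
  expect_equal(sim$truth$map_trace, rep(p$map_baseline,
                                        length(sim$recording$time)))
  expect_equal(sim$truth$response_delay, 30)
})

test_that("physio parameter validation and determinism", {
  expect_error(physio_params(sample_rate = 0), "sample_rate")
  expect_error(physio_params(step_onset = 800, step_duration = 200,
                             duration = 900), "step_duration")
  expect_error(physio_params(response_delay = -1), "response_delay")
  a <- generate_physio(physio_params(duration = 60, step_onset = 20,
                                     step_duration = 20, seed = 11))
  b <- generate_physio(physio_params(duration = 60, step_onset = 20,
                                     step_duration = 20, seed = 11))
  expect_identical(a$recording, b$recording)
})

test_that("trace generator plants the requested rate structure", {
  p <- movie_params(n_frames = 1200, transient_rate = 2,
                    transient_amplitude = 0.5, seed = 8)
  ts <- generate_traces(p, n_traces = 20, dff_noise_sd = 0,
                        stim_frames = c(601, 1200), stim_rate_factor = 3)
  # realized onset counts: second half should be about 3x the first half
  first <- sapply(ts$intervals, function(iv) sum(iv[, 1] <= 600))
  second <- sapply(ts$intervals, function(iv) sum(iv[, 1] > 600))
  expect_gt(sum(second) / sum(first), 2)
  expect_true(all(ts$planted_active_time >= 0 &
                    ts$planted_active_time <= 100))
})

test_that("movies and physio round-trip through disk formats", {
  sim <- generate_movie(movie_params(height = 24, width = 24, n_frames = 6,
                                     seed = 12))
  d <- withr::local_tempdir()
  write_movie_tiff(sim$movie, file.path(d, "m"))
  back <- read_movie_tiff(file.path(d, "m"), frame_interval = 1)
  expect_equal(back$functional, sim$movie$functional, tolerance = 1e-6)
  expect_equal(back$structural, sim$movie$structural, tolerance = 1e-6)
  ph <- generate_physio(physio_params(duration = 20, step_onset = 5,
                                      step_duration = 5, seed = 1))
  f <- file.path(d, "rec.csv")
  write_physio_csv(ph$recording, f, truth = ph$truth)
  back2 <- read_physio_csv(f)
  expect_equal(back2$icp, ph$recording$icp, tolerance = 1e-6)
  expect_equal(back2$sample_rate, ph$recording$sample_rate)
})
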