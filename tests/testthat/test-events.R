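# Event statistics: intervals, active time, frequency, responders,
# peristimulus averages.

test_that("intervals are maximal runs filtered by minimum duration", {
  expect_equal(nrow(intervals_from_mask(rep(FALSE, 10))), 0)
  pat <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  iv1 <- intervals_from_mask(pat, min_duration = 1)
  expect_equal(unname(iv1[, 1]), c(3, 8))
  expect_equal(unname(iv1[, 2]), c(6, 10))
  iv3 <- intervals_from_mask(pat, min_duration = 3)
  expect_equal(nrow(iv3), 1)
  expect_equal(unname(iv3[1, ]), c(3, 6))
})

test_that("active time is conserved coverage over frames", {
  expect_equal(active_time(NULL, 120), 0)
  iv <- cbind(start = c(1, 51), end = c(21, 61))   # 20 + 10 frames
  expect_equal(active_time(iv, 120), 25)
  expect_equal(active_time(cbind(start = 1, end = 121), 120), 100)
  expect_error(active_time(iv, 0), "n_frames")
  # conservation: equals 100 * sum(durations) / n for disjoint intervals
  expect_equal(active_time(iv, 120), 100 * sum(iv[, 2] - iv[, 1]) / 120)
})

test_that("epoch statistics count events starting inside the epoch", {
  iv <- cbind(start = c(10, 40, 70, 100), end = c(14, 44, 74, 104))
  st <- event_stats(iv, c(1, 120), frame_interval = 1)
  expect_equal(st$frequency, 4 / 2)         # 4 events in 2 minutes
  expect_equal(st$mean_duration, 4)
  st2 <- event_stats(cbind(start = integer(0), end = integer(0)), c(1, 60))
  expect_equal(st2$frequency, 0)
  expect_true(is.na(st2$mean_duration))
})

test_that("refinement splits merged events at half prominence", {
  nt <- 60
  x <- numeric(nt)
  x[10:14] <- c(0.3, 1, 0.3, 1, 0.3)      # two peaks, dip below half max
  iv <- cbind(start = 10L, end = 15L)
  out <- refine_intervals(x, iv, detrend_window = 0)
  expect_equal(nrow(out), 2)
  # a single smooth event stays one event
  y <- numeric(nt); y[20:24] <- c(0.4, 0.8, 1, 0.8, 0.4)
  out2 <- refine_intervals(y, cbind(start = 20L, end = 25L),
                           detrend_window = 0)
  expect_equal(nrow(out2), 1)
})

test_that("event frequency is recovered within 20% on hour-long traces", {
  p <- movie_params(n_frames = 3600, frame_interval = 1,
                    transient_rate = 1.5, transient_amplitude = 0.6,
                    seed = 41)
  ts <- generate_traces(p, n_traces = 10, dff_noise_sd = 0.1)
  freqs <- vapply(1:10, function(j) {
    iv <- detect_roi_intervals(ts$observed[, j])
    event_stats(iv, c(1, 3600), 1)$frequency
  }, numeric(1))
  expect_lt(abs(mean(freqs) - 1.5) / 1.5, 0.2)
})

test_that("responder calls: trivial cases, planted responders, null FPR", {
  none <- event_stats(cbind(start = integer(0), end = integer(0)), c(1, 600))
  expect_false(classify_responder(none, none))
  # doubled stimulus rate, 40-minute epochs so the count test has power
  p <- movie_params(n_frames = 7200, transient_rate = 0.8,
                    transient_amplitude = 0.6, seed = 42)
  ts <- generate_traces(p, n_traces = 20, dff_noise_sd = 0.1,
                        stim_frames = c(2401, 4800), stim_rate_factor = 2)
  calls <- vapply(1:20, function(j) {
    iv <- detect_roi_intervals(ts$observed[, j])
    classify_responder(event_stats(iv, c(1, 2400), 1),
                       event_stats(iv, c(2401, 4800), 1))
  }, logical(1))
  expect_gte(mean(calls), 0.7)
  # unchanged rate: false-positive rate <= 10% over 200 simulated ROIs
  ts0 <- generate_traces(movie_params(n_frames = 1800, transient_rate = 2,
                                      transient_amplitude = 0.6, seed = 43),
                         n_traces = 200, dff_noise_sd = 0.1)
  fp <- vapply(1:200, function(j) {
    iv <- detect_roi_intervals(ts0$observed[, j])
    classify_responder(event_stats(iv, c(1, 600), 1),
                       event_stats(iv, c(601, 1200), 1))
  }, logical(1))
  expect_lte(mean(fp), 0.1)
})

test_that("peristimulus averages align, pool and scale correctly", {
  tax <- seq(0, 300, by = 0.5)
  step_tr <- function(t0) list(time = tax, value = as.numeric(tax >= t0))
  traces <- lapply(c(100, 150, 200), step_tr)
  pa <- peristimulus_average(traces, c(100, 150, 200), window = c(30, 60),
                             dt = 0.5)
  expect_equal(pa$n, 3)
  expect_true(all(pa$sem == 0))
  # the planted step sits at t = 0 in the average
  expect_lt(max(pa$mean[pa$time < -1]), 0.01)
  expect_gt(min(pa$mean[pa$time > 1]), 0.99)
  # a trace not covering the window is dropped with a warning
  short <- list(time = seq(140, 160), value = rep(0, 21))
  expect_warning(pa2 <- peristimulus_average(c(traces, list(short)),
                                             c(100, 150, 200, 150),
                                             window = c(30, 60), dt = 0.5),
                 "excluded")
  expect_equal(pa2$n, 3)
  # linearity: average of scaled traces = scaled average
  scaled <- lapply(traces, function(tr) list(time = tr$time,
                                             value = 3 * tr$value))
  pa3 <- peristimulus_average(scaled, c(100, 150, 200), window = c(30, 60),
                              dt = 0.5)
  expect_equal(pa3$mean, 3 * pa$mean)
})

test_that("SEM of noisy replicate traces matches sampling theory", {
  set.seed(5)
  tax <- seq(0, 100, by = 1)
  common <- sin(tax / 10)
  sigma <- 0.5; n <- 8
  traces <- lapply(1:n, function(i)
    list(time = tax, value = common + rnorm(length(tax), 0, sigma)))
  pa <- peristimulus_average(traces, rep(50, n), window = c(40, 40), dt = 1)
  expect_lt(abs(mean(pa$sem) - sigma / sqrt(n)) / (sigma / sqrt(n)), 0.25)
})

test_that("per-ROI event tables carry epochs, classes and responder calls", {
  act <- matrix(FALSE, 120, 2)
  act[c(50:52, 70:72), 1] <- TRUE    # events only during stimulus
  tab <- roi_event_table(act, c(41, 80), frame_interval = 1,
                         classes = c("soma", "process"))
  expect_equal(nrow(tab), 6)         # 2 ROIs x 3 epochs
  s1 <- tab[tab$roi == 1 & tab$epoch == "stimulus", ]
  expect_equal(s1$n_events, 2)
  expect_true(all(tab$active_time >= 0 & tab$active_time <= 100))
  expect_true(all(tab$epoch %in% c("baseline", "stimulus", "post")))
})
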