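# Shared helpers: event matching against planted intervals, textured test
# frames, and a cached small synthetic movie so several test files can
# reuse one simulation.

# Sensitivity / false-discovery of detected intervals vs planted ones,
# matched by any overlap (half-open intervals).
match_events <- function(detected, planted) {
  hits <- 0
  for (k in seq_len(nrow(planted)))
    hits <- hits + any(detected[, 1] < planted[k, 2] &
                         detected[, 2] > planted[k, 1])
  false_det <- 0
  for (k in seq_len(nrow(detected)))
    false_det <- false_det + !any(planted[, 1] < detected[k, 2] &
                                    planted[, 2] > detected[k, 1])
  list(sensitivity = if (nrow(planted) > 0) hits / nrow(planted) else NA,
       fdr = if (nrow(detected) > 0) false_det / nrow(detected) else 0,
       n_detected = nrow(detected), n_planted = nrow(planted))
}

# Band-limited textured frame with strong gradients, for motion tests.
textured_frame <- function(n = 64, seed = 1, sd = 10, offset = 50) {
  set.seed(seed)
  astroca:::gaussian_blur(matrix(rnorm(n * n), n, n), 2) * sd + offset
}

# Per-ROI trace detection chain used by statistics tests: threshold the
# denoised ROI trace at 2 noise SDs, then refine to half-prominence.
detect_roi_intervals <- function(trace, params = detection_params(),
                                 min_duration = 2) {
  act <- detect_transients(trace, estimate_noise_sd(trace), params)
  refine_intervals(trace, intervals_from_mask(act, 1, min_duration))
}

# One small movie with default-style content, cached across tests.
.movie_cache <- new.env(parent = emptyenv())
cached_movie <- function() {
  if (is.null(.movie_cache$sim)) {
    .movie_cache$sim <- generate_movie(movie_params(
      height = 64, width = 64, n_frames = 120, noise_sd = 5,
      rigid_shift_amplitude = 0, nonrigid_amplitude = 0, seed = 7))
  }
  .movie_cache$sim
}
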