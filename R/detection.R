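# Selective averaging and transient detection.
#
# In a moving window, per-pixel dF/F0 traces are projected onto the first
# few principal components of the window and clustered; the cluster
# containing the window's center pixel is selected and its traces averaged.
# The noise SD of the averaged trace is estimated robustly, the trace is
# temporally smoothed and thresholded at `threshold_sd` (default 2) noise
# SDs. Each member pixel accumulates the cluster-average estimate with a
# weight inversely proportional to its distance from the cluster centroid
# in PC space; overlapping windows give most pixels several estimates,
# aggregated by weight-normalized averaging.

#' Detection parameters
#'
#' @param window_size moving-window side in pixels (square).
#' @param window_stride window step in pixels; must be <= `window_size` so
#'   windows overlap or tile without gaps.
#' @param n_pcs number of principal components for the projection.
#' @param n_clusters number of clusters per window (k-means with a
#'   deterministic quantile initialization). The default 5 gives the
#'   clustering room to separate background from up to several cellular
#'   compartments co-occupying one window.
#' @param smoothing_width Gaussian temporal smoothing width (frames)
#'   applied before thresholding.
#' @param threshold_sd threshold in multiples of the noise SD (default 2).
#' @param detrend_window running-median window (frames) subtracted from the
#'   trace before smoothing and thresholding, so slow residual baseline
#'   errors cannot cross the threshold; 0 disables detrending.
#' @return a validated `detection_params` list.
#' @export
detection_params <- function(window_size = 16, window_stride = 8,
                             n_pcs = 5, n_clusters = 5,
                             smoothing_width = 3, threshold_sd = 2,
                             detrend_window = 31) {
  p <- list(window_size = window_size, window_stride = window_stride,
            n_pcs = n_pcs, n_clusters = n_clusters,
            smoothing_width = smoothing_width, threshold_sd = threshold_sd,
            detrend_window = detrend_window)
  check_scalar(p$detrend_window, "detrend_window", lower = 0,
               integerish = TRUE)
  check_scalar(p$window_size, "window_size", lower = 2, integerish = TRUE)
  check_scalar(p$window_stride, "window_stride", lower = 1, integerish = TRUE)
  if (p$window_stride > p$window_size)
    abort_field("window_stride", "must be <= window_size (windows must overlap)")
  check_scalar(p$n_pcs, "n_pcs", lower = 1, integerish = TRUE)
  check_scalar(p$n_clusters, "n_clusters", lower = 2, integerish = TRUE)
  check_scalar(p$smoothing_width, "smoothing_width", lower = 0)
  check_scalar(p$threshold_sd, "threshold_sd", lower = 0, strict_lower = TRUE)
  class(p) <- "detection_params"
  p
}

#' Robust noise SD of a temporal trace
#'
#' Scaled median absolute deviation of first differences
#' (`mad(diff(x)) / sqrt(2)`): insensitive to sparse transients and slow
#' trends, exact for white Gaussian noise.
#'
#' @param trace numeric vector, length >= 10 for a meaningful estimate.
#' @return noise SD estimate (0 for a constant trace).
#' @export
estimate_noise_sd <- function(trace) {
  if (length(trace) < 2L) return(0)
  stats::mad(diff(trace)) / sqrt(2)
}

# Deterministic k-means: centers initialized at quantiles of the ordering
# along the first PC, so results are reproducible without touching the RNG.
kmeans_deterministic <- function(scores, k) {
  ord <- order(scores[, 1])
  qs <- round(stats::quantile(seq_len(nrow(scores)),
                              probs = (seq_len(k) - 0.5) / k, names = FALSE))
  centers <- scores[ord[qs], , drop = FALSE]
  centers <- centers + outer(seq_len(k) * 1e-9, rep(1, ncol(scores)))
  stats::kmeans(scores, centers = centers, iter.max = 50,
                algorithm = "Lloyd")
}

#' Selective averaging within one window
#'
#' Projects each pixel trace of the patch onto the first `n_pcs` principal
#' components, clusters the projections, selects the cluster containing the
#' window's center pixel, and returns the mean trace over that cluster with
#' per-pixel weights `1 / (eps + distance to the cluster centroid in PC
#' space)`. Before the projection each trace is whitened (divided by its
#' robust noise SD and mean-centered), so that dim pixels with large dF/F0
#' noise do not dominate the principal components and signal-sharing pixels
#' separate cleanly from background; the returned average is over the raw
#' (unwhitened) traces.
#'
#' @param patch matrix `n_pixels x n_frames` of dF/F0 traces (rows are the
#'   window's pixels in raster order).
#' @param params a [detection_params()].
#' @param center_index row index of the window's center pixel (default the
#'   middle row).
#' @return list: `trace` (cluster-average), `members` (row indices),
#'   `weights` (per member), `noise_sd` of the averaged trace.
#' @export
denoise_window <- function(patch, params = detection_params(),
                           center_index = NULL) {
  npx <- nrow(patch); nt <- ncol(patch)
  if (is.null(center_index)) center_index <- (npx + 1L) %/% 2L
  k <- params$n_clusters
  n_pcs <- min(params$n_pcs, npx, nt)
  distinct <- nrow(unique(patch)) >= k
  if (!distinct || npx <= k) {
    if (!distinct)
      warning("window has fewer distinct signals than clusters; averaging whole window")
    tr <- colMeans(patch)
    return(list(trace = tr, members = seq_len(npx),
                weights = rep(1, npx), noise_sd = estimate_noise_sd(tr)))
  }
  nsd <- pmax(apply(patch, 1, estimate_noise_sd), 1e-9)
  X <- patch / nsd
  X <- X - rowMeans(X)
  sv <- svd(X, nu = 0, nv = n_pcs)
  scores <- X %*% sv$v
  km <- kmeans_deterministic(scores, k)
  sel <- km$cluster[center_index]
  members <- which(km$cluster == sel)
  d <- sqrt(rowSums(sweep(scores[members, , drop = FALSE], 2,
                          km$centers[sel, ])^2))
  weights <- 1 / (1e-6 + d)
  tr <- colMeans(patch[members, , drop = FALSE])
  list(trace = tr, members = members, weights = weights,
       noise_sd = estimate_noise_sd(tr))
}

#' Threshold a denoised trace into a binary activity vector
#'
#' Smooths the trace with a Gaussian of width `smoothing_width` frames and
#' marks frames where the smoothed trace exceeds
#' `threshold_sd * noise_sd`.
#'
#' @param trace denoised dF/F0 trace.
#' @param noise_sd noise SD of the trace (>= 0).
#' @param params a [detection_params()].
#' @return logical vector, `TRUE` where active.
#' @export
detect_transients <- function(trace, noise_sd, params = detection_params()) {
  check_scalar(noise_sd, "noise_sd", lower = 0)
  x <- trace
  dw <- params$detrend_window
  if (dw > 0 && length(x) > 3) {
    wk <- min(2L * (dw %/% 2L) + 1L, 2L * ((length(x) - 1L) %/% 2L) + 1L)
    x <- x - stats::runmed(x, wk, endrule = "median")
  }
  # smoothing_width is a full width at half maximum (sigma = fwhm / 2.355)
  sm <- smooth_trace(x, sigma = params$smoothing_width / 2.355)
  sm > params$threshold_sd * noise_sd
}

#' Selective averaging over a whole movie
#'
#' Runs [denoise_window()] on an overlapping grid of windows, accumulates
#' weighted per-pixel estimates, aggregates them by weight-normalized
#' averaging, and derives a pixel-frame transient mask from the aggregated
#' traces via [detect_transients()].
#'
#' @param dff a `dff` object from [compute_dff()] or a dF/F0 stack.
#' @param params a [detection_params()].
#' @return list of class `denoised_result`: `denoised` stack,
#'   `transient_mask` logical stack, `weight_sum` matrix, `noise_sd_map`
#'   matrix.
#' @export
selective_average_movie <- function(dff, params = detection_params()) {
  stack <- if (inherits(dff, "dff")) dff$dff else dff
  d <- dim(stack)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  ws <- params$window_size
  if (ws > min(ny, nx))
    abort_field("window_size", "movie must be larger than one window")
  M <- flatten_stack(stack)                     # nt x npx
  acc <- matrix(0, nt, ny * nx)
  w_acc <- numeric(ny * nx)
  stride <- params$window_stride
  y_starts <- unique(pmin(seq(1L, ny, by = stride), ny - ws + 1L))
  x_starts <- unique(pmin(seq(1L, nx, by = stride), nx - ws + 1L))
  for (ys in y_starts) for (xs in x_starts) {
    rows <- ys:(ys + ws - 1L); cols <- xs:(xs + ws - 1L)
    px <- as.vector(outer(rows, (cols - 1L) * ny, `+`))
    patch <- t(M[, px, drop = FALSE])           # npx x nt
    res <- suppressWarnings(denoise_window(patch, params))
    mpx <- px[res$members]
    acc[, mpx] <- acc[, mpx] + outer(res$trace, res$weights)
    w_acc[mpx] <- w_acc[mpx] + res$weights
  }
  # pixels never co-clustered with any window center keep their own raw
  # trace as a self-estimate with unit weight, so every pixel has a
  # positive accumulated weight
  uncovered <- w_acc == 0
  if (any(uncovered)) {
    acc[, uncovered] <- M[, uncovered]
    w_acc[uncovered] <- 1
  }
  den <- sweep(acc, 2, w_acc, `/`)
  noise_map <- apply(den, 2, estimate_noise_sd)
  mask <- vapply(seq_len(ncol(den)), function(j)
    detect_transients(den[, j], noise_map[j], params), logical(nt))
  structure(list(denoised = unflatten_stack(den, ny, nx),
                 transient_mask = unflatten_stack(mask, ny, nx),
                 weight_sum = matrix(w_acc, ny, nx),
                 noise_sd_map = matrix(noise_map, ny, nx),
                 params = params),
            class = "denoised_result")
}

#' Monte-Carlo null of the smoothed threshold rule
#'
#' Estimates the probability that smoothed white Gaussian noise exceeds
#' `threshold_sd` times the (known) noise SD, by simulation with the same
#' smoothing width used for detection.
#'
#' @param params a [detection_params()].
#' @param n_frames trace length per replicate.
#' @param n_reps number of replicates.
#' @param seed RNG seed.
#' @return estimated per-frame exceedance probability.
#' @export
null_active_fraction <- function(params = detection_params(),
                                 n_frames = 500, n_reps = 200, seed = 1) {
  with_seed(seed, {
    hits <- 0; total <- 0
    for (i in seq_len(n_reps)) {
      x <- stats::rnorm(n_frames)
      act <- detect_transients(x, 1, params)
      hits <- hits + sum(act); total <- total + n_frames
    }
    hits / total
  })
}
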