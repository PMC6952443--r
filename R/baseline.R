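# Time-varying baseline fluorescence F0(t).
#
# Two-stage estimate: (1) slow low-rank trends from a truncated SVD of the
# frames-by-pixels matrix, with the temporal components smoothed by
# asymmetric iteratively reweighted least squares so that short transient
# upswings are ignored; (2) local correction of small deviations from the
# low-rank dynamics by temporal smoothing of spatially averaged residuals
# in small overlapping windows. dF/F0 = (F - F0) / max(F0, floor).

#' Flatten an image stack into a frames-by-pixels matrix
#'
#' @param stack array `height x width x n_frames`.
#' @return matrix `n_frames x n_pixels`; each row is one frame unraveled.
#' @export
flatten_stack <- function(stack) {
  d <- dim(stack)
  t(matrix(stack, d[1] * d[2], d[3]))
}

#' @rdname flatten_stack
#' @param M matrix `n_frames x n_pixels`.
#' @param height,width frame dimensions.
#' @export
unflatten_stack <- function(M, height, width) {
  array(t(M), c(height, width, nrow(M)))
}

#' Asymmetric IRLS smoothing of a temporal trace
#'
#' Penalized (second-difference) least squares with asymmetric weights,
#' refit iteratively: samples above the current fit get weight `p`, samples
#' below get `1 - p`. With `p` well below 0.5 the fit tracks the slow
#' component and ignores short positive excursions (transient upswings),
#' while following negative ones.
#'
#' @param y numeric trace, length >= 5, finite.
#' @param n_iter reweighting iterations.
#' @param p weight for upswing samples (0 < p < 0.5 down-weights
#'   upswings).
#' @param lambda smoothness penalty on second differences; larger is
#'   smoother (effective bandwidth roughly `lambda^(1/4)` samples).
#' @param upswing_window width (samples) of the morphological opening that
#'   flags short upswings; excursions longer than this are treated as
#'   trend.
#' @return smoothed trace, same length as `y`.
#' @details Upswing samples are flagged where the trace exceeds its
#'   temporal opening (rolling min then max over `upswing_window`) by two
#'   fast-noise SDs: a criterion on the data, not on the evolving fit,
#'   which keeps the iteration from ratcheting the fit downward at
#'   curvature extrema of genuinely smooth signals. Flagged samples start
#'   at weight `p` and are further bisquare-down-weighted by their
#'   residual each iteration; all other samples keep full weight, so
#'   negative excursions are followed while positive transients are
#'   ignored.
#' @export
irls_smooth <- function(y, n_iter = 10, p = 0.1, lambda = 1e4,
                        upswing_window = 31) {
  if (length(y) < 5L) abort_field("y", "trace must have length >= 5")
  if (!all(is.finite(y))) abort_field("y", "trace must be finite")
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D)
  wk <- min(2L * (upswing_window %/% 2L) + 1L, 2L * ((n - 1L) %/% 2L) + 1L)
  env <- temporal_opening(cbind(y), wk)[, 1]
  s_fast <- max(stats::mad(diff(y)) / sqrt(2), 1e-6 * diff(range(y)),
                .Machine$double.eps)
  up <- (y - env) > 2 * s_fast
  w <- rep(1, n)
  w[up] <- p
  z <- y
  for (it in seq_len(n_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    if (!any(up)) break                  # plain penalized LS: converged
    r <- y - z
    rob <- pmax(1 - (r / (6 * s_fast))^2, 0)^2
    w_new <- w
    w_new[up] <- p * pmax(rob[up], 1e-4)
    if (max(abs(w_new - w)) < 1e-12 && it > 1) break
    w <- w_new
  }
  z
}

#' Low-rank slow-trend estimate of a fluorescence matrix
#'
#' Computes the truncated SVD `F = U S V'` of the frames-by-pixels matrix,
#' smooths the first `r` temporal components (columns of U) with
#' [irls_smooth()], and projects back using only those `r` components. The
#' result has matrix rank at most `r`.
#'
#' @param M matrix `n_frames x n_pixels`.
#' @param r truncation rank (default 20).
#' @param n_iter,p,lambda IRLS parameters, see [irls_smooth()].
#' @return matrix of the same shape as `M`, rank <= `r`.
#' @export
lowrank_trend <- function(M, r = 20, n_iter = 10, p = 0.1, lambda = 1e4) {
  check_scalar(r, "r", lower = 1, integerish = TRUE)
  if (r > min(dim(M))) abort_field("r", "must be <= min(n_frames, n_pixels)")
  nf <- nrow(M)
  ctr <- colMeans(M)
  if (all(abs(sweep(M, 2, ctr)) < 1e-12)) return(M)  # constant movie
  # SVD via the small Gram matrix (n_frames is the short dimension here)
  G <- tcrossprod(M)                       # nf x nf
  eg <- eigen(G, symmetric = TRUE)
  d2 <- pmax(eg$values, 0)
  keep <- seq_len(min(r, sum(d2 > d2[1] * 1e-14)))
  d <- sqrt(d2[keep])
  U <- eg$vectors[, keep, drop = FALSE]
  # Temporal components smoothed in a consistent orientation: SVD signs are
  # arbitrary, so orient each component by the skewness of its fast
  # residual (transient upswings are sparse and positive) before applying
  # the asymmetric fit, then restore the original sign.
  Us <- U
  for (k in seq_along(keep)) {
    u <- U[, k]
    fast <- u - stats::runmed(u, max(3, 2 * (min(15, nf %/% 4)) + 1))
    s <- sign(sum(fast^3))
    if (s == 0) s <- 1
    Us[, k] <- s * irls_smooth(s * u, n_iter, p, lambda)
  }
  V <- crossprod(M, U) %*% diag(1 / d, length(d))   # npx x r
  Us %*% (diag(d, length(d)) %*% t(V))
}

# Morphological opening along the time axis (rows) of a frames-by-pixels
# matrix: rolling minimum then rolling maximum over a centered window.
# Removes upswings shorter than the window while preserving the slow
# envelope; the half-window erosion bias is restored by the dilation.
temporal_opening <- function(M, window) {
  h <- window %/% 2L
  shift_rows <- function(X, s) {
    n <- nrow(X)
    X[pmin(pmax(seq_len(n) + s, 1L), n), , drop = FALSE]
  }
  ero <- M
  for (s in seq_len(h)) ero <- pmin(ero, shift_rows(M, s), shift_rows(M, -s))
  dil <- ero
  for (s in seq_len(h)) dil <- pmax(dil, shift_rows(ero, s), shift_rows(ero, -s))
  dil
}

# Raised-cosine separable window weight (strictly positive interior).
cosine_weight <- function(n) {
  w <- 0.05 + 0.95 * sin(pi * (seq_len(n) - 0.5) / n)^2
  w
}

#' Local correction of residual baseline deviations
#'
#' Adds to the low-rank trend a correction built in small overlapping
#' spatial windows: the residual is spatially averaged per window, smoothed
#' in time (running median over `window_frames` then a light box mean,
#' robust to transient upswings), and blended across windows with
#' raised-cosine weights normalized to unit total weight everywhere.
#'
#' @param movie raw stack `height x width x n_frames`.
#' @param trend low-rank trend stack, same shape.
#' @param window_frames temporal smoothing extent in frames (default 30).
#' @param window_px spatial window side in pixels (default 16), 50% overlap.
#' @return list of class `baseline_estimate`: `F0` stack, `components_used`,
#'   `local_window`.
#' @export
local_correction <- function(movie, trend, window_frames = 30,
                             window_px = 16) {
  d <- dim(movie)
  if (!identical(d, dim(trend)))
    abort_field("trend", "must match the movie shape")
  check_scalar(window_frames, "window_frames", lower = 1,
               upper = d[3], integerish = TRUE)
  check_scalar(window_px, "window_px", lower = 1, upper = min(d[1], d[2]),
               integerish = TRUE)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  resid <- movie - trend
  Rm <- flatten_stack(resid)               # nt x npx
  corr_acc <- matrix(0, nt, ny * nx)
  w_acc <- numeric(ny * nx)
  stride <- max(1L, window_px %/% 2L)
  y_starts <- unique(pmin(seq(1L, ny, by = stride), ny - window_px + 1L))
  x_starts <- unique(pmin(seq(1L, nx, by = stride), nx - window_px + 1L))
  y_starts <- y_starts[y_starts >= 1L]
  x_starts <- x_starts[x_starts >= 1L]
  wk <- max(3L, 2L * (window_frames %/% 2L) + 1L)
  box <- max(1L, window_frames %/% 3L)
  for (ys in y_starts) for (xs in x_starts) {
    rows <- ys:(ys + window_px - 1L)
    cols <- xs:(xs + window_px - 1L)
    px <- as.vector(outer(rows, (cols - 1L) * ny, `+`))
    wspat <- as.vector(outer(cosine_weight(length(rows)),
                             cosine_weight(length(cols))))
    tr <- as.numeric(Rm[, px, drop = FALSE] %*% (wspat / sum(wspat)))
    # reject residual upswings (transients) before smoothing: clip at the
    # temporal opening (envelope) plus one robust noise SD
    env <- temporal_opening(cbind(tr), wk)[, 1]
    sdw <- stats::mad(diff(tr)) / sqrt(2)
    tr <- stats::runmed(pmin(tr, env + 0.5 * sdw), wk, endrule = "median")
    if (box > 1) tr <- smooth_trace(tr, sigma = box / 2)
    corr_acc[, px] <- corr_acc[, px] + outer(tr, wspat)
    w_acc[px] <- w_acc[px] + wspat
  }
  corr <- sweep(corr_acc, 2, w_acc, `/`)
  F0 <- trend + unflatten_stack(corr, ny, nx)
  structure(list(F0 = F0, components_used = NA_integer_,
                 local_window = c(frames = window_frames, px = window_px)),
            class = "baseline_estimate")
}

#' Estimate the time-varying baseline of a movie
#'
#' Convenience wrapper: low-rank trend (rank `r`, IRLS-smoothed temporal
#' components) followed by local windowed correction.
#'
#' @param stack raw stack `height x width x n_frames`.
#' @param r truncation rank.
#' @inheritParams lowrank_trend
#' @inheritParams local_correction
#' @param local apply the local-correction stage?
#' @param clip_k upswing rejection before the SVD: each pixel trace is
#'   clipped at its running median plus `clip_k` noise SDs, so sparse
#'   transient power cannot dominate the top singular components while the
#'   slow level of every pixel is preserved. Set to `Inf` to disable.
#' @param clip_window running-median window (frames) for the clipping
#'   ceiling; must exceed the longest expected transient.
#' @return a `baseline_estimate` (see [local_correction()]).
#' @export
estimate_baseline <- function(stack, r = 20, n_iter = 10, p = 0.1,
                              lambda = 1e4, window_frames = 30,
                              window_px = 16, local = TRUE,
                              clip_k = 2, clip_window = 31) {
  d <- dim(stack)
  r_eff <- min(r, d[3], d[1] * d[2])
  M <- flatten_stack(stack)
  if (is.finite(clip_k)) {
    wk <- min(2L * (clip_window %/% 2L) + 1L, 2L * ((d[3] - 1L) %/% 2L) + 1L)
    env <- temporal_opening(M, wk)
    sd_px <- apply(M, 2, function(x) stats::mad(diff(x)) / sqrt(2))
    Mwork <- pmin(M, sweep(env, 2, clip_k * sd_px, `+`))
  } else Mwork <- M
  T_ <- lowrank_trend(Mwork, r_eff, n_iter, p, lambda)
  trend <- unflatten_stack(T_, d[1], d[2])
  if (!local) {
    return(structure(list(F0 = trend, components_used = r_eff,
                          local_window = NULL),
                     class = "baseline_estimate"))
  }
  out <- local_correction(stack, trend,
                          window_frames = min(window_frames, d[3]),
                          window_px = min(window_px, d[1], d[2]))
  out$components_used <- r_eff
  out
}

#' Compute dF/F0
#'
#' @param stack raw stack.
#' @param baseline a `baseline_estimate` or an F0 stack of the same shape.
#' @param floor positive intensity floor applied to F0 in the denominator;
#'   defaults to 1% of the global movie mean, keeping dF/F0 finite in dark
#'   regions.
#' @return list of class `dff`: `dff` stack (dimensionless) and `floor`.
#' @export
compute_dff <- function(stack, baseline, floor = NULL) {
  F0 <- if (inherits(baseline, "baseline_estimate")) baseline$F0 else baseline
  if (!identical(dim(stack), dim(F0)))
    abort_field("baseline", "must match the movie shape")
  if (is.null(floor)) floor <- 0.01 * mean(stack)
  check_scalar(floor, "floor", lower = 0, strict_lower = TRUE)
  dff <- (stack - F0) / pmax(F0, floor)
  structure(list(dff = dff, floor = floor), class = "dff")
}

#' Check that a baseline stays inside a percentile band of the raw trace
#'
#' Automated surrogate for visual inspection of F0: in sliding windows the
#' baseline should lie within the 5th-60th percentile band of the raw
#' trace. Returns the fraction of samples (over all pixels supplied) inside
#' the band.
#'
#' @param raw_trace,f0_trace numeric matrices `n_frames x n_traces` (or
#'   vectors).
#' @param window sliding window length in frames.
#' @param lower,upper percentile bounds (fractions).
#' @return fraction in `[0, 1]` of samples whose F0 lies inside the band.
#' @export
baseline_band_check <- function(raw_trace, f0_trace, window = 60,
                                lower = 0.05, upper = 0.60) {
  raw_trace <- as.matrix(raw_trace); f0_trace <- as.matrix(f0_trace)
  nt <- nrow(raw_trace)
  window <- min(window, nt)
  inside <- 0; total <- 0
  for (j in seq_len(ncol(raw_trace))) {
    for (t in seq_len(nt)) {
      a <- max(1, t - window %/% 2); b <- min(nt, t + window %/% 2)
      q <- stats::quantile(raw_trace[a:b, j], c(lower, upper), names = FALSE)
      inside <- inside + (f0_trace[t, j] >= q[1] && f0_trace[t, j] <= q[2])
      total <- total + 1
    }
  }
  inside / total
}
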