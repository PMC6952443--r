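# Lateral motion correction: rigid-body shifts first (FFT cross-correlation
# against a template with parabolic subpixel refinement), then dense
# combined local-global (CLG) optical flow estimated on the structural
# channel and applied to both channels.
#
# Coordinate convention (used package-wide): displacements are content
# displacements in (row, col) = (y, x) order; a field d aligns the moving
# frame to the fixed frame via moving(y + dy, x + dx).

#' Motion field container
#'
#' @param rigid_shifts `n_frames x 2` matrix of per-frame (dy, dx) content
#'   shifts in pixels.
#' @param flow_fields optional list of per-frame dense displacement fields,
#'   each `list(dy, dx)` of matrices.
#' @param reference_frame index of the reference frame or `"template"`.
#' @return an object of class `motion_field`.
#' @export
motion_field <- function(rigid_shifts, flow_fields = NULL,
                         reference_frame = "template") {
  if (!is.matrix(rigid_shifts) || ncol(rigid_shifts) != 2L)
    abort_field("rigid_shifts", "must be an n_frames x 2 matrix")
  if (!all(is.finite(rigid_shifts)))
    abort_field("rigid_shifts", "must be finite")
  if (!is.null(flow_fields)) {
    ok <- all(vapply(flow_fields, function(f)
      all(is.finite(f$dy)) && all(is.finite(f$dx)), logical(1)))
    if (!ok) abort_field("flow_fields", "must be finite everywhere")
  }
  structure(list(rigid_shifts = rigid_shifts, flow_fields = flow_fields,
                 reference_frame = reference_frame),
            class = "motion_field")
}

# Temporal median frame: robust template unaffected by sparse transients.
template_frame <- function(stack) {
  apply(stack, c(1, 2), stats::median)
}

resolve_reference <- function(stack, reference) {
  if (identical(reference, "template")) template_frame(stack)
  else if (is.numeric(reference) && length(reference) == 1L)
    stack[, , reference]
  else if (is.matrix(reference)) reference
  else abort_field("reference", "must be \"template\", a frame index, or a matrix")
}

# Cross-correlation shift of `moving` relative to `fixed` via FFT, with
# optional x10 upsampled-DFT subpixel refinement (the cross-correlation is
# re-evaluated on a 0.1 px grid around the integer peak by matrix-multiply
# inverse DFT). Returns the content displacement (dy, dx) such that
# moving(y + dy, x + dx) ~ fixed(y, x).
xcorr_shift <- function(fixed, moving, subpixel = TRUE, upsample = 10) {
  ny <- nrow(fixed); nx <- ncol(fixed)
  f <- fixed - mean(fixed); m <- moving - mean(moving)
  if (sum(f^2) == 0 || sum(m^2) == 0) {
    warning("constant frame: cross-correlation undefined, returning zero shift")
    return(c(0, 0))
  }
  # Hann window: suppresses border content, which otherwise acts as a
  # spurious zero-shift image component (borders are shared between the
  # frames up to edge effects) and biases the peak toward zero
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  W <- outer(hann(ny), hann(nx))
  f <- f * W; m <- m * W
  CC <- stats::fft(m) * Conj(stats::fft(f))
  cc <- Re(stats::fft(CC, inverse = TRUE))
  pk <- which.max(cc)
  py <- ((pk - 1) %% ny) + 1L
  px <- ((pk - 1) %/% ny) + 1L
  dy <- py - 1; dx <- px - 1
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  if (subpixel) {
    freq <- function(n) { k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n; k }
    uy <- dy + seq(-1, 1, by = 1 / upsample)
    ux <- dx + seq(-1, 1, by = 1 / upsample)
    Ey <- exp(2i * pi * outer(uy, freq(ny)) / ny)       # n_u x ny
    Ex <- exp(2i * pi * outer(freq(nx), ux) / nx)       # nx x n_u
    cc_up <- Re(Ey %*% CC %*% Ex)
    pk2 <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
    dy <- uy[pk2[1]]; dx <- ux[pk2[2]]
  }
  c(dy, dx)
}

#' Estimate per-frame rigid shifts against a reference
#'
#' FFT cross-correlation of every frame with the reference (by default the
#' temporal median frame, robust to transients), with parabolic subpixel
#' refinement of the correlation peak.
#'
#' @param stack image stack `height x width x n_frames` (use the structural
#'   channel).
#' @param reference `"template"` (temporal median), a frame index, or a
#'   reference matrix.
#' @param subpixel refine the correlation peak to subpixel precision?
#' @return `n_frames x 2` matrix of content shifts (dy, dx), in pixels.
#'   With the `"template"` reference the shifts are re-centered to zero
#'   mean, i.e. reported relative to the movie's temporal mean position:
#'   registration is only defined up to a constant, the median template's
#'   implicit position depends on the shift trajectory, and centering both
#'   fixes the gauge and minimizes total resampling.
#' @export
estimate_rigid_shifts <- function(stack, reference = "template",
                                  subpixel = TRUE) {
  if (length(dim(stack)) != 3L || dim(stack)[3] < 2L)
    abort_field("stack", "needs at least 2 frames")
  ref <- resolve_reference(stack, reference)
  nt <- dim(stack)[3]
  sh <- t(vapply(seq_len(nt), function(t)
    xcorr_shift(ref, stack[, , t], subpixel = subpixel), numeric(2)))
  if (is.numeric(reference) && length(reference) == 1L)
    sh[reference, ] <- c(0, 0)
  else if (identical(reference, "template"))
    sh <- sweep(sh, 2, colMeans(sh))
  colnames(sh) <- c("dy", "dx")
  sh
}

# Spatial gradients by central differences (edge replication).
image_gradients <- function(m) {
  gy <- (shift_replicate(m, -1, 0) - shift_replicate(m, 1, 0)) / 2
  gx <- (shift_replicate(m, 0, -1) - shift_replicate(m, 0, 1)) / 2
  list(gy = gy, gx = gx)
}

downsample2 <- function(m) {
  ny <- nrow(m) %/% 2L; nx <- ncol(m) %/% 2L
  m <- m[seq_len(2 * ny), seq_len(2 * nx), drop = FALSE]
  (m[seq(1, 2 * ny, 2), seq(1, 2 * nx, 2)] +
     m[seq(2, 2 * ny, 2), seq(1, 2 * nx, 2)] +
     m[seq(1, 2 * ny, 2), seq(2, 2 * nx, 2)] +
     m[seq(2, 2 * ny, 2), seq(2, 2 * nx, 2)]) / 4
}

upsample_to <- function(m, ny, nx) {
  yy <- matrix(seq(1, nrow(m), length.out = ny), ny, nx)
  xx <- matrix(seq(1, ncol(m), length.out = nx), ny, nx, byrow = TRUE)
  matrix(bilinear_sample(m, yy, xx), ny, nx)
}

# One pyramid level of CLG flow refinement. fixed/moving are same-size
# matrices; (u, v) = (dy, dx) initial fields, updated in place.
clg_refine <- function(fixed, moving, u, v, lambda, n_iter, rho = 2) {
  warped <- warp_frame(moving, u, v)
  g <- image_gradients((warped + fixed) / 2)
  It <- warped - fixed
  # structure tensor, smoothed over scale rho (local term of CLG)
  J11 <- gaussian_blur(g$gy * g$gy, rho)
  J22 <- gaussian_blur(g$gx * g$gx, rho)
  J12 <- gaussian_blur(g$gy * g$gx, rho)
  J13 <- gaussian_blur(g$gy * It, rho)
  J23 <- gaussian_blur(g$gx * It, rho)
  du <- u * 0; dv <- v * 0
  denom <- lambda + J11 + J22
  nb_mean <- function(m)
    (shift_replicate(m, 1, 0) + shift_replicate(m, -1, 0) +
       shift_replicate(m, 0, 1) + shift_replicate(m, 0, -1)) / 4
  for (it in seq_len(n_iter)) {
    ub <- nb_mean(du); vb <- nb_mean(dv)
    du <- ub - (J11 * ub + J12 * vb + J13) / denom
    dv <- vb - (J12 * ub + J22 * vb + J23) / denom
  }
  list(u = u + du, v = v + dv)
}

#' Dense combined local-global (CLG) optical flow between two frames
#'
#' Estimates the displacement field aligning `moving` to `fixed` by the CLG
#' energy: a Lucas-Kanade-style structure-tensor data term (tensor entries
#' smoothed over a local integration scale) combined with a
#' Horn-Schunck-style global smoothness term, solved by fixed-point
#' iteration on a coarse-to-fine pyramid with warping between levels.
#'
#' @param fixed,moving numeric matrices of identical shape.
#' @param lambda smoothness (regularization) weight; larger gives smoother
#'   fields.
#' @param n_iter fixed-point iterations per pyramid level.
#' @param pyramid_levels number of pyramid levels (1 = no pyramid).
#' @param rho integration scale (pixels) for the structure tensor.
#' @return `list(dy, dx)` displacement matrices: content displacement such
#'   that `moving(y + dy, x + dx)` matches `fixed(y, x)`.
#' @export
estimate_clg_flow <- function(fixed, moving, lambda = 40, n_iter = 60,
                              pyramid_levels = 3, rho = 2) {
  if (!identical(dim(fixed), dim(moving)))
    abort_field("moving", "must match the shape of `fixed`")
  check_scalar(lambda, "lambda", lower = 0, strict_lower = TRUE)
  if (stats::var(as.vector(fixed)) == 0 || stats::var(as.vector(moving)) == 0) {
    warning("zero-variance frame: returning zero flow field")
    z <- fixed * 0
    return(list(dy = z, dx = z))
  }
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(pyramid_levels - 1)) {
    if (min(dim(pyr_f[[l]])) < 16) break
    pyr_f[[l + 1]] <- downsample2(gaussian_blur(pyr_f[[l]], 1))
    pyr_m[[l + 1]] <- downsample2(gaussian_blur(pyr_m[[l]], 1))
  }
  L <- length(pyr_f)
  u <- pyr_f[[L]] * 0; v <- u
  for (l in rev(seq_len(L))) {
    f <- pyr_f[[l]]; m <- pyr_m[[l]]
    if (l < L) {
      u <- upsample_to(u, nrow(f), ncol(f)) * (nrow(f) / nrow(pyr_f[[l + 1]]))
      v <- upsample_to(v, nrow(f), ncol(f)) * (ncol(f) / ncol(pyr_f[[l + 1]]))
    }
    for (w in 1:2) {   # two warp/re-linearization sweeps per level
      res <- clg_refine(f, m, u, v, lambda, n_iter)
      u <- res$u; v <- res$v
    }
  }
  list(dy = u, dx = v)
}

#' Apply a motion field to a two-channel movie
#'
#' Both channels are resampled identically (bilinear interpolation, edge
#' replication at the borders) by the rigid shift composed with the dense
#' flow of each frame. Output shape equals input shape.
#'
#' @param movie a [two_channel_movie()].
#' @param motion a [motion_field()].
#' @return the corrected [two_channel_movie()].
#' @export
apply_correction <- function(movie, motion) {
  nt <- n_frames(movie)
  if (nrow(motion$rigid_shifts) != nt)
    abort_field("motion", "rigid_shifts rows must equal the frame count")
  func <- movie$functional; struct <- movie$structural
  for (t in seq_len(nt)) {
    dy <- motion$rigid_shifts[t, 1]; dx <- motion$rigid_shifts[t, 2]
    fl <- motion$flow_fields[[t]]
    if (!is.null(fl)) {
      if (!identical(dim(fl$dy), dim(movie$functional)[1:2]))
        abort_field("motion", "flow field shape must match the movie")
      DY <- fl$dy + dy; DX <- fl$dx + dx
    } else if (dy == 0 && dx == 0) next
    else { DY <- dy; DX <- dx }
    func[, , t] <- warp_frame(movie$functional[, , t], DY, DX)
    struct[, , t] <- warp_frame(movie$structural[, , t], DY, DX)
  }
  two_channel_movie(pmax(func, 0), pmax(struct, 0), movie$frame_interval,
                    movie$pixel_size)
}

#' Full two-stage motion correction of a movie
#'
#' Estimates rigid shifts on the structural channel against the temporal
#' median template, applies them to both channels, then estimates dense CLG
#' flow per frame on the rigid-corrected structural channel and applies it
#' to both channels. The structural channel drives all estimates; both
#' channels receive identical geometric transforms.
#'
#' @param movie a [two_channel_movie()].
#' @param reference reference spec for [estimate_rigid_shifts()].
#' @param lambda,n_iter,pyramid_levels,rho CLG parameters, see
#'   [estimate_clg_flow()].
#' @param subpixel subpixel rigid refinement?
#' @param flow estimate the dense non-rigid stage as well?
#' @return list with `movie` (corrected) and `motion` (a [motion_field()]
#'   holding the estimates).
#' @export
correct_motion <- function(movie, reference = "template", lambda = 40,
                           n_iter = 60, pyramid_levels = 3, rho = 2,
                           subpixel = TRUE, flow = TRUE) {
  sh <- estimate_rigid_shifts(movie$structural, reference, subpixel)
  rigid_only <- motion_field(sh, NULL, reference)
  m1 <- apply_correction(movie, rigid_only)
  flows <- NULL
  if (flow) {
    ref <- resolve_reference(m1$structural, reference)
    flows <- lapply(seq_len(n_frames(m1)), function(t)
      estimate_clg_flow(ref, m1$structural[, , t], lambda = lambda,
                        n_iter = n_iter, pyramid_levels = pyramid_levels,
                        rho = rho))
    zero_rigid <- matrix(0, n_frames(m1), 2)
    m2 <- apply_correction(m1, motion_field(zero_rigid, flows, reference))
  } else m2 <- m1
  list(movie = m2, motion = motion_field(sh, flows, reference))
}
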