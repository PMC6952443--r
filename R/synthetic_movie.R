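# Synthetic two-channel movie generator with full ground truth.
#
# Emulates the statistical structure the analysis assumes: astrocyte-shaped
# ROIs (somas, processes, perivascular endfeet) on a square field of view,
# planted exponential-kinetics Ca2+ transients (multiplicative on baseline),
# slow low-rank multiplicative drift, lateral motion (rigid random walk +
# smooth sinusoidal non-rigid fields), and additive Gaussian (optionally
# Poisson) noise.

#' Parameters of the synthetic movie generator
#'
#' Defaults describe a desk-scale recording: a 128 x 128 px field of view
#' imaged at 1 Hz for 5 minutes, with sparse multiplicative transients and
#' slow rank-3 baseline drift.
#'
#' @param height,width field of view in pixels.
#' @param n_frames number of frames.
#' @param frame_interval seconds between frames.
#' @param n_somas,n_processes,n_endfeet ROI counts per compartment class.
#' @param transient_rate planted event rate, events per minute per ROI.
#' @param transient_amplitude peak transient size in dF/F0 units
#'   (multiplicative on baseline).
#' @param rise_tau,decay_tau transient kinetics in seconds
#'   (difference-of-exponentials, `rise_tau < decay_tau`).
#' @param drift_rank number of separable (temporal x spatial) drift
#'   components; the planted baseline has matrix rank at most
#'   `drift_rank + 1`.
#' @param drift_amplitude peak drift as a fraction of baseline intensity.
#' @param rigid_shift_amplitude peak rigid shift in pixels (smooth random
#'   walk).
#' @param nonrigid_amplitude peak non-rigid displacement in pixels
#'   (low-frequency separable sinusoids).
#' @param noise_sd additive Gaussian noise standard deviation, intensity
#'   units (`noise_model = "gaussian"`); ignored for Poisson noise.
#' @param noise_model `"gaussian"` (default; keeps the noise-sd ground truth
#'   exact) or `"poisson"` (shot noise with variance equal to the mean).
#' @param active_fraction fraction of the peak amplitude above which a frame
#'   counts as planted-active (0.5 = full width at half maximum).
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return a validated `synthetic_movie_params` list.
#' @export
movie_params <- function(height = 128, width = 128, n_frames = 300,
                         frame_interval = 1,
                         n_somas = 6, n_processes = 8, n_endfeet = 5,
                         transient_rate = 1.5, transient_amplitude = 0.6,
                         rise_tau = 0.5, decay_tau = 2,
                         drift_rank = 3, drift_amplitude = 0.1,
                         rigid_shift_amplitude = 2, nonrigid_amplitude = 0.75,
                         noise_sd = 5, noise_model = c("gaussian", "poisson"),
                         active_fraction = 0.5, seed = 1) {
  p <- list(height = height, width = width, n_frames = n_frames,
            frame_interval = frame_interval, n_somas = n_somas,
            n_processes = n_processes, n_endfeet = n_endfeet,
            transient_rate = transient_rate,
            transient_amplitude = transient_amplitude,
            rise_tau = rise_tau, decay_tau = decay_tau,
            drift_rank = drift_rank, drift_amplitude = drift_amplitude,
            rigid_shift_amplitude = rigid_shift_amplitude,
            nonrigid_amplitude = nonrigid_amplitude,
            noise_sd = noise_sd, noise_model = match.arg(noise_model),
            active_fraction = active_fraction, seed = seed)
  check_scalar(p$height, "height", lower = 8, integerish = TRUE)
  check_scalar(p$width, "width", lower = 8, integerish = TRUE)
  check_scalar(p$n_frames, "n_frames", lower = 2, integerish = TRUE)
  check_scalar(p$frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  for (f in c("n_somas", "n_processes", "n_endfeet"))
    check_scalar(p[[f]], f, lower = 0, integerish = TRUE)
  check_scalar(p$transient_rate, "transient_rate", lower = 0)
  check_scalar(p$transient_amplitude, "transient_amplitude", lower = 0)
  check_scalar(p$rise_tau, "rise_tau", lower = 0, strict_lower = TRUE)
  check_scalar(p$decay_tau, "decay_tau", lower = 0, strict_lower = TRUE)
  check_scalar(p$drift_rank, "drift_rank", lower = 0, integerish = TRUE)
  if (p$drift_rank >= min(p$n_frames, p$height * p$width))
    abort_field("drift_rank", "must be < min(n_frames, n_pixels)")
  check_scalar(p$drift_amplitude, "drift_amplitude", lower = 0, upper = 0.9)
  check_scalar(p$rigid_shift_amplitude, "rigid_shift_amplitude", lower = 0)
  check_scalar(p$nonrigid_amplitude, "nonrigid_amplitude", lower = 0)
  check_scalar(p$noise_sd, "noise_sd", lower = 0)
  check_scalar(p$active_fraction, "active_fraction", lower = 0, upper = 1)
  check_scalar(p$seed, "seed", integerish = TRUE)
  class(p) <- "synthetic_movie_params"
  p
}

# --- geometry painters ------------------------------------------------------

# Approximate Euclidean distance (chamfer 1 / sqrt(2)) to a mask, computed
# only up to max_dist; farther pixels get Inf.
chamfer_dist <- function(mask, max_dist) {
  d <- ifelse(mask, 0, Inf)
  n_it <- ceiling(max_dist) + 1L
  for (it in seq_len(n_it)) {
    d_new <- d
    for (o in list(c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1),
                   c(1, 1, sqrt(2)), c(1, -1, sqrt(2)),
                   c(-1, 1, sqrt(2)), c(-1, -1, sqrt(2)))) {
      d_new <- pmin(d_new, shift_replicate(d, o[1], o[2]) + o[3])
    }
    if (identical(d_new, d)) break
    d <- d_new
  }
  d
}

# Smooth vessel path across the field; returns sampled (y, x) points.
vessel_path <- function(height, width, phase) {
  x <- seq(1, width, length.out = 4L * width)
  y <- height / 2 + 0.22 * height * sin(2 * pi * (x / width) * 1.3 + phase)
  cbind(y = y, x = x)
}

paint_ellipse <- function(lab, claimed, label, cy, cx, ry, rx, theta) {
  ny <- nrow(lab); nx <- ncol(lab)
  yy <- matrix(seq_len(ny), ny, nx) - cy
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  u <- yy * cos(theta) + xx * sin(theta)
  v <- -yy * sin(theta) + xx * cos(theta)
  inside <- (u / ry)^2 + (v / rx)^2 <= 1
  if (any(inside & claimed)) return(NULL)
  lab[inside] <- label
  lab
}

rasterize_path <- function(ny, nx, pts, half_width) {
  mask <- matrix(FALSE, ny, nx)
  ij <- unique(cbind(round(pts[, 1]), round(pts[, 2])))
  ok <- ij[, 1] >= 1 & ij[, 1] <= ny & ij[, 2] >= 1 & ij[, 2] <= nx
  mask[ij[ok, , drop = FALSE]] <- TRUE
  if (half_width > 0) {
    d <- chamfer_dist(mask, half_width + 1)
    mask <- d <= half_width
  }
  mask
}

# Paint all ROI classes; returns list(labels, classes, vessel_mask).
paint_rois <- function(p) {
  ny <- p$height; nx <- p$width
  lab <- matrix(0L, ny, nx)
  classes <- character(0)
  vp <- vessel_path(ny, nx, phase = stats::runif(1, 0, 2 * pi))
  vessel_radius <- 3.5
  vessel_core <- rasterize_path(ny, nx, vp, 0)
  vdist <- chamfer_dist(vessel_core, vessel_radius + 5)
  vessel_mask <- vdist <= vessel_radius
  claimed <- vessel_mask
  nxt <- 1L
  margin <- 10
  # keep distinct structures >= 2 px apart so they remain individually
  # resolvable, as the scored compartments are in real fields of view
  buffer <- function(mask) chamfer_dist(mask, 3) <= 2

  # the perivascular interface belongs to endfeet: keep soma and process
  # bodies out of a margin around the vessel
  vessel_zone <- vdist <= vessel_radius + 4

  # somas: filled ellipses, radii 4-8 px
  forbidden <- buffer(claimed)
  for (i in seq_len(p$n_somas)) {
    for (attempt in 1:60) {
      cy <- stats::runif(1, margin, ny - margin)
      cx <- stats::runif(1, margin, nx - margin)
      ry <- stats::runif(1, 4, 8); rx <- stats::runif(1, 4, 8)
      th <- stats::runif(1, 0, pi)
      res <- paint_ellipse(lab, forbidden | vessel_zone, nxt, cy, cx, ry, rx, th)
      if (!is.null(res)) {
        lab <- res; classes <- c(classes, "soma"); nxt <- nxt + 1L
        forbidden <- buffer(claimed | lab > 0)
        break
      }
    }
  }

  # processes: thick curved polylines, width 2-3 px; kept clear of the
  # vessel (a parenchymal process that hugs a vessel would be an endfoot)
  for (i in seq_len(p$n_processes)) {
    for (attempt in 1:60) {
      y0 <- stats::runif(1, margin, ny - margin)
      x0 <- stats::runif(1, margin, nx - margin)
      heading <- stats::runif(1, 0, 2 * pi)
      n_steps <- round(stats::runif(1, 25, 45))
      pts <- matrix(0, n_steps, 2)
      yy <- y0; xx <- x0
      for (s in seq_len(n_steps)) {
        heading <- heading + stats::rnorm(1, 0, 0.22)
        yy <- yy + 1.4 * sin(heading); xx <- xx + 1.4 * cos(heading)
        pts[s, ] <- c(yy, xx)
      }
      hw <- stats::runif(1, 1, 1.5)   # half width -> 2-3 px wide
      m <- rasterize_path(ny, nx, pts, hw)
      m <- m & !forbidden & !vessel_zone
      cc <- label_components(m, 8)
      if (max(cc) == 0) next
      sizes <- tabulate(cc[cc > 0])
      m <- cc == which.max(sizes)
      if (sum(m) < 14) next
      lab[m] <- nxt; classes <- c(classes, "process"); nxt <- nxt + 1L
      forbidden <- buffer(claimed | lab > 0)
      break
    }
  }

  # endfeet: annular arcs hugging the vessel
  n_path <- nrow(vp)
  arc_centers <- round(seq(0.1, 0.9, length.out = max(p$n_endfeet, 1)) * n_path)
  for (i in seq_len(p$n_endfeet)) {
    placed <- FALSE
    for (attempt in 1:20) {
      ctr <- arc_centers[i] + round(stats::rnorm(1, 0, n_path / 40))
      ctr <- min(max(ctr, 30), n_path - 30)
      arc_len <- round(stats::runif(1, 25, 45))
      idx <- seq(max(1, ctr - arc_len), min(n_path, ctr + arc_len))
      arc_core <- rasterize_path(ny, nx, vp[idx, , drop = FALSE], 0)
      ad <- chamfer_dist(arc_core, vessel_radius + 4)
      m <- ad <= vessel_radius + 3 & vdist > vessel_radius
      # one-sided arc: keep pixels on a random side of the vessel
      side <- sample(c(-1, 1), 1)
      yy_rel <- matrix(seq_len(ny), ny, nx) -
        matrix(stats::approx(vp[, 2], vp[, 1], xout = seq_len(nx),
                             rule = 2)$y, ny, nx, byrow = TRUE)
      m <- m & (sign(yy_rel) == side)
      m <- m & !forbidden
      cc <- label_components(m, 8)
      if (max(cc) == 0) next
      sizes <- tabulate(cc[cc > 0])
      m <- cc == which.max(sizes)
      if (sum(m) < 10) next
      lab[m] <- nxt; classes <- c(classes, "endfoot"); nxt <- nxt + 1L
      forbidden <- buffer(claimed | lab > 0)
      placed <- TRUE
      break
    }
    if (!placed) next
  }

  list(labels = lab, classes = classes, vessel_mask = vessel_mask)
}

# --- temporal pieces --------------------------------------------------------

# Difference-of-exponentials transient kernel, normalized to peak 1.
transient_kernel <- function(t, rise_tau, decay_tau) {
  if (decay_tau <= rise_tau) decay_tau <- rise_tau * 1.5
  k <- exp(-t / decay_tau) - exp(-t / rise_tau)
  k[t < 0] <- 0
  tpk <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  pk <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  k / pk
}

# Plant Poisson-timed transients for one ROI; returns the dF/F0 trace and
# half-open active intervals [start, end) in frame indices.
plant_roi_events <- function(p, times) {
  nt <- p$n_frames
  dur_min <- nt * p$frame_interval / 60
  n_ev <- stats::rpois(1, p$transient_rate * dur_min)
  s <- numeric(nt)
  if (n_ev > 0) {
    onsets <- sort(stats::runif(n_ev, 0, (nt - 2) * p$frame_interval))
    for (on in onsets)
      s <- s + p$transient_amplitude *
        transient_kernel(times - on, p$rise_tau, p$decay_tau)
  }
  active <- s >= p$active_fraction * p$transient_amplitude
  list(trace = s, intervals = runs_to_intervals(active))
}

# Convert a logical vector into half-open [start, end) run intervals.
runs_to_intervals <- function(active) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

# Smooth low-rank multiplicative drift: list(u = Nf x r, g = list of maps).
make_drift <- function(p) {
  if (p$drift_rank == 0 || p$drift_amplitude == 0)
    return(NULL)
  tt <- seq_len(p$n_frames) / p$n_frames
  u <- sapply(seq_len(p$drift_rank), function(k) {
    sin(2 * pi * tt * stats::runif(1, 0.4, 1.6) + stats::runif(1, 0, 2 * pi))
  })
  u <- matrix(u, ncol = p$drift_rank)
  g <- lapply(seq_len(p$drift_rank), function(k) {
    m <- gaussian_blur(matrix(stats::rnorm(p$height * p$width),
                              p$height, p$width), sigma = p$height / 6)
    m / max(abs(m))
  })
  list(u = u * (p$drift_amplitude / p$drift_rank), g = g)
}

# Smooth rigid-shift random walk, zero-mean, peak |shift| = amplitude.
make_rigid_shifts <- function(p) {
  nt <- p$n_frames
  if (p$rigid_shift_amplitude == 0) return(matrix(0, nt, 2))
  sh <- sapply(1:2, function(i) {
    w <- cumsum(stats::rnorm(nt))
    w <- smooth_trace(w, sigma = 5)
    w <- w - mean(w)
    w / max(abs(w)) * p$rigid_shift_amplitude
  })
  matrix(sh, nt, 2, dimnames = list(NULL, c("dy", "dx")))
}

# Separable low-frequency non-rigid displacement model.
make_nonrigid <- function(p) {
  if (p$nonrigid_amplitude == 0) return(NULL)
  ny <- p$height; nx <- p$width; nt <- p$n_frames
  yy <- matrix(seq_len(ny) / ny, ny, nx)
  xx <- matrix(seq_len(nx) / nx, ny, nx, byrow = TRUE)
  tt <- seq_len(nt) / nt
  comp <- function() {
    sp <- sin(2 * pi * (yy * stats::runif(1, 0.5, 1.2) +
                          stats::runif(1, 0, 1))) *
      sin(2 * pi * (xx * stats::runif(1, 0.5, 1.2) + stats::runif(1, 0, 1)))
    tc <- sin(2 * pi * (tt * stats::runif(1, 0.6, 1.4) + stats::runif(1, 0, 1)))
    tc <- tc - mean(tc)   # reference geometry = temporal mean position
    list(map = sp, trace = tc)
  }
  m <- list(y = comp(), x = comp())
  peak <- max(max(abs(m$y$map)) * max(abs(m$y$trace)),
              max(abs(m$x$map)) * max(abs(m$x$trace)))
  m$scale <- p$nonrigid_amplitude / peak
  m
}

#' Ground-truth displacement field for one frame
#'
#' Returns the planted content displacement (rigid + non-rigid) for frame
#' `t` of a synthetic movie, as a list with `dy` and `dx` matrices in
#' pixels, (row, col) order.
#'
#' @param truth ground-truth list from [generate_movie()].
#' @param t frame index.
#' @export
motion_field_at <- function(truth, t) {
  ny <- nrow(truth$labels); nx <- ncol(truth$labels)
  dy <- matrix(truth$rigid_shifts[t, 1], ny, nx)
  dx <- matrix(truth$rigid_shifts[t, 2], ny, nx)
  nr <- truth$nonrigid
  if (!is.null(nr)) {
    dy <- dy + nr$scale * nr$y$map * nr$y$trace[t]
    dx <- dx + nr$scale * nr$x$map * nr$x$trace[t]
  }
  list(dy = dy, dx = dx)
}

#' Generate a synthetic two-channel movie with ground truth
#'
#' The functional channel is built as
#' `baseline drift x (1 + planted transients)`, warped by planted motion,
#' plus noise; the structural channel is a static marker texture warped by
#' the same motion. Everything planted is recorded in the returned ground
#' truth. Identical seeds give bit-identical output.
#'
#' @param params a [movie_params()] object.
#' @return list with elements `movie` (a [two_channel_movie()]) and `truth`
#'   (labels, classes, vessel mask, per-ROI transient traces and half-open
#'   active intervals, planted active time in percent, the clean baseline
#'   stack, rigid shifts, non-rigid displacement model, and noise sd).
#' @export
generate_movie <- function(params) {
  p <- if (inherits(params, "synthetic_movie_params")) params
       else do.call(movie_params, params)
  with_seed(p$seed, {
    ny <- p$height; nx <- p$width; nt <- p$n_frames
    geo <- paint_rois(p)
    n_roi <- max(geo$labels)

    # static channel bases (band-limited so gradients are informative)
    func_base <- matrix(40, ny, nx)
    func_base[geo$labels > 0] <- 150
    func_base <- gaussian_blur(func_base, 0.8) +
      gaussian_blur(matrix(stats::rnorm(ny * nx, 0, 12), ny, nx), 2)
    func_base <- pmax(func_base, 5)
    struct_base <- matrix(20, ny, nx)
    struct_base[geo$labels > 0] <- 160
    struct_base[geo$vessel_mask] <- 6
    struct_base <- gaussian_blur(struct_base, 0.8) +
      gaussian_blur(matrix(stats::rnorm(ny * nx, 0, 10), ny, nx), 2)
    struct_base <- pmax(struct_base, 1)

    drift <- make_drift(p)
    times <- (seq_len(nt) - 1L) * p$frame_interval
    ev <- lapply(seq_len(n_roi), function(i) plant_roi_events(p, times))
    roi_traces <- if (n_roi > 0)
      sapply(ev, `[[`, "trace") else matrix(0, nt, 0)
    roi_traces <- matrix(roi_traces, nrow = nt)
    intervals <- lapply(ev, `[[`, "intervals")
    active_time <- vapply(ev, function(e)
      100 * sum(pmin(e$intervals[, 2], nt + 1L) - e$intervals[, 1]) / nt,
      numeric(1))

    rigid <- make_rigid_shifts(p)
    nonrigid <- make_nonrigid(p)
    truth <- list(labels = geo$labels, classes = geo$classes,
                  vessel_mask = geo$vessel_mask,
                  roi_traces = roi_traces, transient_intervals = intervals,
                  planted_active_time = active_time,
                  rigid_shifts = rigid, nonrigid = nonrigid,
                  noise_sd = if (p$noise_model == "gaussian") p$noise_sd else NA_real_,
                  params = p)

    baseline_movie <- array(0, c(ny, nx, nt))
    func <- array(0, c(ny, nx, nt))
    struct <- array(0, c(ny, nx, nt))
    has_motion <- p$rigid_shift_amplitude > 0 || p$nonrigid_amplitude > 0
    roi_of_px <- geo$labels
    for (t in seq_len(nt)) {
      dmap <- if (is.null(drift)) 0 else {
        acc <- matrix(0, ny, nx)
        for (k in seq_along(drift$g)) acc <- acc + drift$u[t, k] * drift$g[[k]]
        acc
      }
      B <- func_base * (1 + dmap)
      baseline_movie[, , t] <- B
      mult <- matrix(1, ny, nx)
      if (n_roi > 0) {
        on <- roi_of_px > 0
        mult[on] <- 1 + roi_traces[t, roi_of_px[on]]
      }
      Fc <- B * mult
      Sc <- struct_base * (1 + dmap)
      if (has_motion) {
        # content moves by +d: observed(y, x) = clean(y - dy, x - dx), so
        # warp_frame(observed, +d) undoes the motion (package convention)
        mf <- motion_field_at(truth, t)
        Fc <- warp_frame(Fc, -mf$dy, -mf$dx)
        Sc <- warp_frame(Sc, -mf$dy, -mf$dx)
      }
      func[, , t] <- Fc
      struct[, , t] <- Sc
    }
    if (p$noise_model == "gaussian" && p$noise_sd > 0) {
      func <- func + array(stats::rnorm(length(func), 0, p$noise_sd), dim(func))
      struct <- struct +
        array(stats::rnorm(length(struct), 0, p$noise_sd), dim(struct))
      func <- pmax(func, 0); struct <- pmax(struct, 0)
    } else if (p$noise_model == "poisson") {
      func <- array(stats::rpois(length(func), pmax(func, 0)), dim(func))
      struct <- array(stats::rpois(length(struct), pmax(struct, 0)), dim(struct))
    }
    truth$baseline_movie <- baseline_movie
    movie <- two_channel_movie(func, struct, p$frame_interval)
    list(movie = movie, truth = truth)
  })
}

#' Generate synthetic per-ROI dF/F0 traces with ground truth
#'
#' Trace-level counterpart of [generate_movie()] for testing event
#' statistics on long recordings without the imaging stages: plants
#' Poisson-timed difference-of-exponentials transients directly in dF/F0
#' units and adds white Gaussian noise. The event rate can change by a
#' factor inside a stimulus window (inhomogeneous Poisson), emulating
#' stimulus-responsive ROIs.
#'
#' @param params a [movie_params()] object (uses `n_frames`,
#'   `frame_interval`, `transient_rate`, `transient_amplitude`, `rise_tau`,
#'   `decay_tau`, `active_fraction`, `seed`).
#' @param n_traces number of traces.
#' @param dff_noise_sd additive noise SD in dF/F0 units.
#' @param stim_frames optional `c(first, last)` frames of a stimulus
#'   window.
#' @param stim_rate_factor event-rate multiplier inside the window.
#' @return list: `observed` (`n_frames x n_traces`), `clean`,
#'   `intervals` (per trace, half-open), `planted_active_time` (%),
#'   `n_events` planted per trace.
#' @export
generate_traces <- function(params, n_traces = 1, dff_noise_sd = 0.05,
                            stim_frames = NULL, stim_rate_factor = 1) {
  p <- if (inherits(params, "synthetic_movie_params")) params
       else do.call(movie_params, params)
  with_seed(p$seed, {
    nt <- p$n_frames
    times <- (seq_len(nt) - 1L) * p$frame_interval
    clean <- matrix(0, nt, n_traces)
    intervals <- vector("list", n_traces)
    n_events <- integer(n_traces)
    rate_of <- rep(p$transient_rate, nt)
    if (!is.null(stim_frames))
      rate_of[stim_frames[1]:stim_frames[2]] <-
        p$transient_rate * stim_rate_factor
    lam_per_frame <- rate_of * p$frame_interval / 60
    for (j in seq_len(n_traces)) {
      n_ev_frame <- stats::rpois(nt, lam_per_frame)
      onsets <- rep(times, n_ev_frame) +
        stats::runif(sum(n_ev_frame), 0, p$frame_interval)
      s <- numeric(nt)
      for (on in onsets)
        s <- s + p$transient_amplitude *
          transient_kernel(times - on, p$rise_tau, p$decay_tau)
      clean[, j] <- s
      intervals[[j]] <- runs_to_intervals(
        s >= p$active_fraction * p$transient_amplitude)
      n_events[j] <- length(onsets)
    }
    observed <- clean +
      matrix(stats::rnorm(nt * n_traces, 0, dff_noise_sd), nt, n_traces)
    active <- vapply(intervals, function(iv)
      100 * sum(pmin(iv[, 2], nt + 1L) - iv[, 1]) / nt, numeric(1))
    list(observed = observed, clean = clean, intervals = intervals,
         planted_active_time = active, n_events = n_events)
  })
}

#' Write a synthetic dataset to disk
#'
#' Movies go to multi-page TIFF (per channel), the ROI label image to TIFF,
#' and the scalar/tabular ground truth (classes, intervals, planted active
#' time, rigid shifts, noise sd, parameters) to JSON.
#'
#' @param sim output of [generate_movie()].
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- write_movie_tiff(sim$movie, file.path(dir, "movie"))
  labf <- file.path(dir, "roi_labels.tif")
  write_stack_tiff(array(sim$truth$labels / max(1, max(sim$truth$labels)),
                         c(dim(sim$truth$labels), 1)), labf)
  gt <- list(classes = sim$truth$classes,
             planted_active_time = sim$truth$planted_active_time,
             transient_intervals = sim$truth$transient_intervals,
             rigid_shifts = sim$truth$rigid_shifts,
             noise_sd = sim$truth$noise_sd,
             params = unclass(sim$truth$params))
  gtf <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, gtf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, labf, gtf))
}
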