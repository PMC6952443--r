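# ROI segmentation from the structural channel and trace extraction.
#
# Bright regions are segmented by adaptive thresholding against the local
# mean of an 11 x 11 pixel block in each frame; contiguous regions that are
# foreground in more than 50% of frames (strict) become ROIs, filtered by a
# minimum area. Compartment classes (soma / process / endfoot) are assigned
# from shape descriptors and vessel adjacency; marker-negative cells are
# accepted only as externally supplied masks.

#' Segmentation parameters
#'
#' @param block_size odd side of the local-mean block (default 11).
#' @param persistence_fraction fraction of frames a pixel must be
#'   foreground, strict inequality (default 0.5).
#' @param connectivity 4 or 8 (default 8).
#' @param min_roi_area minimum ROI area in pixels.
#' @param contrast_floor additive offset above the local mean a pixel must
#'   exceed to count as foreground, in intensity units. Scale it together
#'   with any global rescaling of the channel.
#' @param global_floor additional global brightness requirement:
#'   `"otsu"` (default) thresholds the temporal mean image by Otsu's
#'   method, a number is used directly, `NA` disables it. Prevents the
#'   blur halo of bright structures adjacent to dark regions (e.g.
#'   perivascular endfeet next to the vessel lumen) from passing the
#'   purely local test.
#' @return a validated `segmentation_params` list.
#' @export
segmentation_params <- function(block_size = 11, persistence_fraction = 0.5,
                                connectivity = 8, min_roi_area = 6,
                                contrast_floor = 10, global_floor = "otsu") {
  p <- list(block_size = block_size,
            persistence_fraction = persistence_fraction,
            connectivity = connectivity, min_roi_area = min_roi_area,
            contrast_floor = contrast_floor, global_floor = global_floor)
  if (!(identical(p$global_floor, "otsu") ||
        (length(p$global_floor) == 1L &&
           (is.na(p$global_floor) || is.numeric(p$global_floor)))))
    abort_field("global_floor", "must be \"otsu\", a number, or NA")
  check_scalar(p$block_size, "block_size", lower = 3, integerish = TRUE)
  if (p$block_size %% 2 == 0)
    abort_field("block_size", "must be odd")
  check_scalar(p$persistence_fraction, "persistence_fraction", lower = 0,
               upper = 1)
  if (p$persistence_fraction <= 0 || p$persistence_fraction >= 1)
    abort_field("persistence_fraction", "must be strictly between 0 and 1")
  if (!p$connectivity %in% c(4, 8))
    abort_field("connectivity", "must be 4 or 8")
  check_scalar(p$min_roi_area, "min_roi_area", lower = 1, integerish = TRUE)
  check_scalar(p$contrast_floor, "contrast_floor", lower = 0)
  class(p) <- "segmentation_params"
  p
}

# Otsu's between-class-variance threshold on a numeric sample.
otsu_threshold <- function(x, nbins = 256) {
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2])))
    return(-Inf)   # constant image: no global cut
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1),
                      plot = FALSE)
  w <- h$counts; m <- h$mids
  tot <- sum(w); cw <- cumsum(w); cm <- cumsum(w * m)
  mu <- cm[length(cm)] / tot
  sb <- (mu * cw - cm)^2 / (cw * (tot - cw))
  sb[!is.finite(sb)] <- 0
  m[which.max(sb)]
}

roi_table <- function(label_image, classes = NULL) {
  n <- max(label_image)
  if (n == 0)
    return(data.frame(label = integer(0), class = character(0),
                      area = integer(0), centroid_y = numeric(0),
                      centroid_x = numeric(0)))
  idx <- which(label_image > 0)
  lab <- label_image[idx]
  yy <- ((idx - 1) %% nrow(label_image)) + 1
  xx <- ((idx - 1) %/% nrow(label_image)) + 1
  area <- tabulate(lab, n)
  data.frame(label = seq_len(n),
             class = if (is.null(classes)) rep(NA_character_, n) else classes,
             area = area,
             centroid_y = tapply(yy, factor(lab, seq_len(n)), mean),
             centroid_x = tapply(xx, factor(lab, seq_len(n)), mean),
             row.names = NULL)
}

#' Segment ROIs from the structural channel
#'
#' Per frame, foreground = pixel intensity greater than the sliding
#' `block_size x block_size` local mean plus `contrast_floor`. The
#' persistence map (fraction of frames foreground) is thresholded strictly
#' at `persistence_fraction`, labeled into contiguous regions under the
#' declared connectivity, and filtered by `min_roi_area`.
#'
#' @param structural image stack `height x width x n_frames` (>= 2 frames).
#' @param params a [segmentation_params()].
#' @return list of class `roi_set`: `label_image` (0 = background), `rois`
#'   (data frame: label, class, area, centroid), `persistence` map,
#'   `params`.
#' @export
segment_rois <- function(structural, params = segmentation_params()) {
  d <- dim(structural)
  if (length(d) != 3L || d[3] < 2L)
    abort_field("structural", "needs a stack with >= 2 frames")
  bright <- TRUE
  if (identical(params$global_floor, "otsu")) {
    mim <- apply(structural, c(1, 2), mean)
    bright <- mim > otsu_threshold(as.vector(mim))
  } else if (!is.na(params$global_floor)) {
    mim <- apply(structural, c(1, 2), mean)
    bright <- mim > params$global_floor
  }
  persist <- matrix(0, d[1], d[2])
  for (t in seq_len(d[3])) {
    fr <- structural[, , t]
    fg <- (fr > box_mean(fr, params$block_size) + params$contrast_floor) &
      bright
    persist <- persist + fg
  }
  persist <- persist / d[3]
  mask <- persist > params$persistence_fraction   # strict: exactly 50% is background
  lab <- label_components(mask, params$connectivity)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= params$min_roi_area)
    remap <- integer(length(areas))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  structure(list(label_image = lab, rois = roi_table(lab),
                 persistence = persist, params = params),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs", nrow(x$rois)))
  if (!all(is.na(x$rois$class)))
    cat(": ", paste(sprintf("%s=%d", names(table(x$rois$class)),
                            table(x$rois$class)), collapse = ", "))
  cat("\n")
  invisible(x)
}

# Shape descriptors of one ROI mask: area, eccentricity (second moments),
# solidity (area / convex hull area).
roi_shape <- function(idx, ny) {
  yy <- ((idx - 1) %% ny) + 1
  xx <- ((idx - 1) %/% ny) + 1
  n <- length(idx)
  cy <- mean(yy); cx <- mean(xx)
  myy <- mean((yy - cy)^2) + 1 / 12
  mxx <- mean((xx - cx)^2) + 1 / 12
  mxy <- mean((yy - cy) * (xx - cx))
  tr <- myy + mxx
  det_ <- myy * mxx - mxy^2
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det_, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det_, 0))
  ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  hull_area <- if (n >= 3) {
    h <- grDevices::chull(xx, yy)
    px <- xx[h]; py <- yy[h]
    abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2 + n^0 * 0
  } else 0
  # pad the hull by half a pixel per vertex so single-row shapes get
  # non-zero solidity denominators
  solidity <- if (hull_area > 0) min(n / (hull_area + sqrt(n)), 1) else 1
  list(area = n, eccentricity = ecc, solidity = solidity,
       centroid = c(cy, cx))
}

#' Classify ROI compartments
#'
#' Heuristic shape-based assignment: an ROI adjacent to the vessel mask
#' (within `vessel_dist` pixels) is an endfoot; otherwise a compact ROI
#' (high solidity, area above `soma_min_area`, moderate eccentricity) is a
#' soma; elongated ROIs (high eccentricity) are processes. Marker-negative
#' cells are never inferred; supply them externally if delineated.
#'
#' @param rois a `roi_set` from [segment_rois()].
#' @param vessel_map optional logical matrix of vessel pixels; without it
#'   the endfoot class is unavailable (a message is emitted).
#' @param soma_min_area minimum soma area, pixels.
#' @param solidity_min minimum soma solidity.
#' @param eccentricity_max maximum soma eccentricity.
#' @param vessel_dist adjacency distance to the vessel, pixels.
#' @return the `roi_set` with `rois$class` filled in.
#' @export
classify_compartments <- function(rois, vessel_map = NULL,
                                  soma_min_area = 30, solidity_min = 0.85,
                                  eccentricity_max = 0.92, vessel_dist = 3) {
  if (nrow(rois$rois) == 0) abort_field("rois", "must contain at least one ROI")
  lab <- rois$label_image
  ny <- nrow(lab)
  near_vessel <- NULL
  if (!is.null(vessel_map)) {
    vd <- chamfer_dist(vessel_map, vessel_dist + 1)
    near_vessel <- vd <= vessel_dist
  } else {
    message("no vessel map supplied: endfoot class unavailable")
  }
  cls <- character(nrow(rois$rois))
  for (i in seq_len(nrow(rois$rois))) {
    idx <- which(lab == rois$rois$label[i])
    sh <- roi_shape(idx, ny)
    touches_vessel <- !is.null(near_vessel) && any(near_vessel[idx])
    cls[i] <- if (touches_vessel) "endfoot"
    else if (sh$solidity >= solidity_min && sh$area >= soma_min_area &&
             sh$eccentricity <= eccentricity_max) "soma"
    else "process"
  }
  rois$rois$class <- cls
  rois
}

#' Extract per-ROI traces from a denoised movie
#'
#' @param denoised a `denoised_result` from [selective_average_movie()] or
#'   a stack.
#' @param rois a `roi_set`.
#' @return matrix `n_frames x n_rois` of mean dF/F0 per ROI, columns
#'   ordered by label.
#' @export
extract_traces <- function(denoised, rois) {
  stack <- if (inherits(denoised, "denoised_result")) denoised$denoised
           else denoised
  d <- dim(stack)
  if (!identical(d[1:2], dim(rois$label_image)))
    abort_field("rois", "label image must match the movie frame shape")
  n <- max(rois$label_image)
  M <- flatten_stack(stack)      # nt x npx
  out <- matrix(0, d[3], n)
  for (i in seq_len(n)) {
    idx <- which(rois$label_image == i)
    out[, i] <- rowMeans(M[, idx, drop = FALSE])
  }
  colnames(out) <- rois$rois$label
  out
}

#' Per-ROI activity from the denoised movie
#'
#' Extracts each ROI's mean denoised dF/F0 trace and thresholds it with
#' [detect_transients()] (2 noise SDs of the ROI trace by default), giving
#' the frame-by-frame elevation indicator the event statistics consume.
#'
#' @param denoised a `denoised_result` from [selective_average_movie()].
#' @param rois a `roi_set`.
#' @param params a [detection_params()]; defaults to the parameters the
#'   denoised result was computed with.
#' @return logical matrix `n_frames x n_rois`.
#' @export
roi_activity <- function(denoised, rois, params = NULL) {
  if (is.null(params))
    params <- denoised$params %||% detection_params()
  traces <- extract_traces(denoised, rois)
  out <- vapply(seq_len(ncol(traces)), function(i)
    detect_transients(traces[, i], estimate_noise_sd(traces[, i]), params),
    logical(nrow(traces)))
  matrix(out, nrow = nrow(traces))
}

#' Bulk fluorescence trace in a fixed region
#'
#' Mean fluorescence inside `mask` per frame, expressed as dF/F0 against
#' the mean of a pre-stimulus window. Intended for bulk (non-cellular)
#' microprobe recordings.
#'
#' @param stack intensity stack.
#' @param mask logical matrix, non-empty.
#' @param pre_frames integer vector of pre-stimulus frame indices.
#' @return numeric dF/F0 trace.
#' @export
bulk_trace <- function(stack, mask, pre_frames) {
  if (!any(mask)) abort_field("mask", "must be non-empty")
  if (length(pre_frames) == 0)
    abort_field("pre_frames", "pre-stimulus window must be non-empty")
  M <- flatten_stack(stack)
  tr <- rowMeans(M[, which(mask), drop = FALSE])
  f0 <- mean(tr[pre_frames])
  (tr - f0) / f0
}
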