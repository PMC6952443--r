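#' Two-channel fluorescence movie
#'
#' Container for a registered pair of image stacks: a functional channel
#' (Ca2+ indicator, e.g. OGB) and a structural channel (astrocyte marker,
#' e.g. SR101). Both stacks are numeric arrays of dimension
#' `c(height, width, n_frames)` in (row, col) = (y, x) order and share
#' timing. Intensities must be non-negative.
#'
#' @param functional,structural numeric arrays `height x width x n_frames`.
#' @param frame_interval frame spacing in seconds.
#' @param pixel_size optional pixel pitch in micrometers.
#' @return an object of class `two_channel_movie`.
#' @export
two_channel_movie <- function(functional, structural, frame_interval,
                              pixel_size = NULL) {
  if (!is.array(functional) || length(dim(functional)) != 3L)
    abort_field("functional", "must be a 3-D array (height x width x frames)")
  if (!is.array(structural) || length(dim(structural)) != 3L)
    abort_field("structural", "must be a 3-D array (height x width x frames)")
  if (!identical(dim(functional), dim(structural)))
    abort_field("structural", "channel dimensions must match the functional channel")
  check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  if (any(functional < 0) || any(structural < 0))
    abort_field("functional/structural", "intensities must be non-negative")
  structure(list(functional = functional, structural = structural,
                 frame_interval = frame_interval, pixel_size = pixel_size),
            class = "two_channel_movie")
}

#' @export
print.two_channel_movie <- function(x, ...) {
  d <- dim(x$functional)
  cat(sprintf("<two_channel_movie> %d x %d px, %d frames, dt = %g s\n",
              d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' @export
dim.two_channel_movie <- function(x) dim(x$functional)

n_frames <- function(movie) dim(movie$functional)[3]

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are affinely rescaled to `[0, 1]` and stored as 32-bit
#' floats, one page per frame; the scale and offset go to a JSON sidecar
#' (`<path>.json`) so [read_stack_tiff()] restores the original units.
#'
#' @param stack numeric array `height x width x n_frames`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  scaled <- (stack - lo) / scale
  pages <- lapply(seq_len(dim(stack)[3]), function(i) scaled[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' Restores original intensity units when the JSON sidecar written by
#' [write_stack_tiff()] is present.
#'
#' @param path TIFF file.
#' @return numeric array `height x width x n_frames`.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  out <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    out <- out * meta$scale + meta$offset
  }
  out
}

#' Write a two-channel movie to TIFF
#'
#' Either one file per channel (`interleave = FALSE`, writes
#' `<stem>_functional.tif` and `<stem>_structural.tif`) or a single file
#' with channels interleaved frame by frame.
#'
#' @param movie a [two_channel_movie()].
#' @param stem output path stem (without extension).
#' @param interleave write a single interleaved file?
#' @return character vector of files written.
#' @export
write_movie_tiff <- function(movie, stem, interleave = FALSE) {
  if (interleave) {
    d <- dim(movie$functional)
    inter <- array(0, c(d[1], d[2], 2 * d[3]))
    inter[, , seq(1, 2 * d[3], by = 2)] <- movie$functional
    inter[, , seq(2, 2 * d[3], by = 2)] <- movie$structural
    f <- paste0(stem, ".tif")
    write_stack_tiff(inter, f)
    f
  } else {
    f1 <- paste0(stem, "_functional.tif")
    f2 <- paste0(stem, "_structural.tif")
    write_stack_tiff(movie$functional, f1)
    write_stack_tiff(movie$structural, f2)
    c(f1, f2)
  }
}

#' Read a two-channel movie written by [write_movie_tiff()]
#'
#' @param stem path stem used when writing.
#' @param frame_interval frame spacing in seconds.
#' @param interleave was the movie written interleaved?
#' @inheritParams two_channel_movie
#' @return a [two_channel_movie()].
#' @export
read_movie_tiff <- function(stem, frame_interval, interleave = FALSE,
                            pixel_size = NULL) {
  if (interleave) {
    inter <- read_stack_tiff(paste0(stem, ".tif"))
    nt <- dim(inter)[3] %/% 2L
    two_channel_movie(inter[, , seq(1, 2 * nt, by = 2), drop = FALSE],
                      inter[, , seq(2, 2 * nt, by = 2), drop = FALSE],
                      frame_interval, pixel_size)
  } else {
    two_channel_movie(read_stack_tiff(paste0(stem, "_functional.tif")),
                      read_stack_tiff(paste0(stem, "_structural.tif")),
                      frame_interval, pixel_size)
  }
}
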