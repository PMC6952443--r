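# Shared low-level helpers: argument checks, image resampling, separable
# smoothing, connected-component labeling, local RNG scoping.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a message naming the offending argument
#' @noRd
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a finite numeric scalar")
  if (strict_lower && x <= lower)
    abort_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    abort_field(field, sprintf("must be >= %g", lower))
  if (x > upper) abort_field(field, sprintf("must be <= %g", upper))
  if (integerish && x != round(x))
    abort_field(field, "must be a whole number")
  invisible(x)
}

#' Evaluate an expression with a private, seeded RNG stream
#'
#' Saves and restores the caller's `.Random.seed`, so generators are
#' reproducible without perturbing the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stage label, stably and
# within 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

#' Bilinear sampling with edge replication
#'
#' Samples `img` at (possibly fractional) coordinates; coordinates outside
#' the image are clamped to the border, replicating edge values.
#'
#' @param img numeric matrix.
#' @param y,x numeric vectors/matrices of row and column sample positions
#'   (1-based).
#' @return numeric object shaped like `y`.
#' @noRd
bilinear_sample <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 1), ny)
  x <- pmin(pmax(x, 1), nx)
  y0 <- pmin(floor(y), ny - 1L); x0 <- pmin(floor(x), nx - 1L)
  if (ny == 1L) y0 <- rep(1, length(y))
  if (nx == 1L) x0 <- rep(1, length(x))
  fy <- y - y0; fx <- x - x0
  y1 <- pmin(y0 + 1, ny); x1 <- pmin(x0 + 1, nx)
  i00 <- (x0 - 1) * ny + y0
  i10 <- (x0 - 1) * ny + y1
  i01 <- (x1 - 1) * ny + y0
  i11 <- (x1 - 1) * ny + y1
  v <- img[i00] * (1 - fy) * (1 - fx) + img[i10] * fy * (1 - fx) +
    img[i01] * (1 - fy) * fx + img[i11] * fy * fx
  out <- y * 0 + v
  out
}

#' Warp a frame by a displacement field
#'
#' Convention used package-wide: displacements describe where image content
#' moved to, in (row, col) = (y, x) order. `warp_frame` pulls each output
#' pixel from `frame` at (y + dy, x + dx): applying it with the content
#' displacement undoes that displacement for smooth fields.
#' @noRd
warp_frame <- function(frame, dy, dx) {
  ny <- nrow(frame); nx <- ncol(frame)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  matrix(bilinear_sample(frame, yy + dy, xx + dx), ny, nx)
}

# Shift a matrix by whole pixels with edge replication (used by smoothing
# and flow solvers); s = c(dy, dx) moves content by +s.
shift_replicate <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  ri <- pmin(pmax(seq_len(ny) - dy, 1L), ny)
  ci <- pmin(pmax(seq_len(nx) - dx, 1L), nx)
  m[ri, ci, drop = FALSE]
}

# Separable convolution with a 1-D kernel along rows then columns,
# edge-replicated. Kernel must be odd-length.
sep_conv <- function(m, k) {
  h <- (length(k) - 1L) %/% 2L
  out <- m * 0
  for (i in seq_along(k)) out <- out + k[i] * shift_replicate(m, i - h - 1L, 0L)
  out2 <- out * 0
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_replicate(out, 0L, i - h - 1L)
  out2
}

gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sep_conv(m, gaussian_kernel(sigma))
}

# Sliding-window box mean over a square neighborhood (edge replication),
# via separable uniform kernels.
box_mean <- function(m, size) {
  k <- rep(1 / size, size)
  sep_conv(m, k)
}

#' Gaussian smoothing of a 1-D trace (edge-replicated)
#' @noRd
smooth_trace <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel(sigma)
  h <- (length(k) - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, k, sides = 2))[(h + 1):(h + length(x))]
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix, 0 = background, components numbered from 1 in
#'   raster order of their first pixel.
#' @noRd
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  ny <- nrow(mask); nx <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, ny, nx)
  if (length(idx) == 0L) return(lab)
  pos <- match(seq_len(ny * nx), idx)      # linear index -> vertex id
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  r <- ((idx - 1L) %% ny) + 1L
  cc <- ((idx - 1L) %/% ny) + 1L
  for (o in offs) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= ny & c2 >= 1L & c2 <= nx
    nb <- (c2[ok] - 1L) * ny + r2[ok]
    v2 <- pos[nb]
    keep <- !is.na(v2)
    if (any(keep))
      edges <- c(edges, rbind(which(ok)[keep], v2[keep]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components in raster order of first occurrence
  first <- match(unique(comp), comp)
  ord <- order(idx[first])
  remap <- integer(max(comp)); remap[unique(comp)[ord]] <- seq_along(ord)
  lab[idx] <- remap[comp]
  lab
}

# Robust numerical rank: number of singular values above tol * largest.
numerical_rank <- function(M, tol = 1e-8) {
  d <- svd(M, nu = 0, nv = 0)$d
  sum(d > tol * d[1])
}
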