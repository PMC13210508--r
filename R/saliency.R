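#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Count gaze fixations into a pixel grid
#'
#' Every sample weighs 1 (no duration weighting): each in-bounds merged
#' sample increments exactly one cell, the pixel containing its 0-based
#' coordinate. Missing samples and samples outside `[0, width) x [0,
#' height)` are dropped and tallied separately.
#'
#' @param samples data.frame with columns `x`, `y` (e.g. from
#'   [mergeBinocular()]); `NA` rows count as missing.
#' @param width,height grid size in pixels.
#' @return A [CountGrid-class]; `sum(gridCounts(.))` equals the number of
#'   in-bounds samples.
#' @examples
#' g <- countFixations(data.frame(x = rep(10, 300), y = rep(10, 300)), 64, 64)
#' gridCounts(g)[11, 11]  # 300 (0-based cell (10,10))
#' @export
countFixations <- function(samples, width, height) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width > 0L, height > 0L)
  x <- samples$x; y <- samples$y
  miss <- is.na(x) | is.na(y)
  cx <- floor(x[!miss]); cy <- floor(y[!miss])
  inb <- cx >= 0 & cx < width & cy >= 0 & cy < height
  idx <- (cy[inb] + 1) + cx[inb] * height  # column-major cell index
  counts <- matrix(tabulate(idx, nbins = height * width), height, width)
  new("CountGrid", counts = counts, nMissing = sum(miss),
      nOutOfBounds = sum(!inb))
}

#' Truncated Gaussian convolution kernel
#'
#' One-dimensional kernel of odd length `size`, normalized to sum 1. The
#' two-dimensional smoothing kernel is its outer product, so smoothing is
#' applied separably.
#'
#' @param size odd kernel length in pixels.
#' @param sigma standard deviation in pixels.
#' @return Numeric vector of length `size`.
#' @export
gaussianKernel <- function(size, sigma) {
  stopifnot(size >= 1, size %% 2 == 1, sigma > 0)
  h <- (size - 1) / 2
  k <- dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

## Banded convolution matrix for zero-padded 1-D convolution along an axis.
.convBand <- function(n, kernel) {
  h <- (length(kernel) - 1) / 2
  d <- outer(seq_len(n), seq_len(n), function(i, j) i - j)
  k <- numeric(2 * n + 1)
  k[(-h:h) + n + 1] <- kernel
  matrix(k[d + n + 1], n, n)
}

#' Smooth a fixation grid into a saliency map
#'
#' Convolves the counts with a truncated 2-D Gaussian (zero padding outside
#' the grid: gaze cannot land off screen) and normalizes. The reference
#' parameters are a 168x168 kernel with sigma 24 at full 1920x1080 capture;
#' an even size has no center pixel and would shift the map by half a
#' pixel, so it is bumped to the next odd size (168 -> 169).
#'
#' With `normalize = "max"` the peak equals 1 ("a heat map between 0 and
#' 1"); `"sum"` rescales to total mass 1 for distribution-style metrics.
#' An all-zero grid maps to an all-zero map.
#'
#' @param grid a [CountGrid-class] (or a numeric count matrix).
#' @param kernelSize kernel side length in pixels; even values are bumped
#'   to the next odd integer.
#' @param sigma Gaussian SD in pixels.
#' @param normalize "max" or "sum".
#' @param kind kind of the resulting [SaliencyMap-class].
#' @return A [SaliencyMap-class] the same size as the grid.
#' @examples
#' g <- countFixations(data.frame(x = 32, y = 32), 64, 64)
#' m <- smoothToMap(g, kernelSize = 33, sigma = 4)
#' max(mapValues(m))  # 1 at the fixation
#' @export
smoothToMap <- function(grid, kernelSize = 169, sigma = 24,
                        normalize = c("max", "sum"), kind = "PSM") {
  normalize <- match.arg(normalize)
  counts <- if (is(grid, "CountGrid")) gridCounts(grid) else as.matrix(grid)
  if (kernelSize %% 2 == 0) kernelSize <- kernelSize + 1
  k <- gaussianKernel(kernelSize, sigma)
  sm <- .convBand(nrow(counts), k) %*% counts %*% .convBand(ncol(counts), k)
  sm[sm < 0] <- 0  # clip tiny negative round-off
  tot <- if (normalize == "max") max(sm) else sum(sm)
  if (tot > 0) sm <- sm / tot
  SaliencyMap(sm, kind)
}

#' Aggregate per-subject fixation grids into a universal saliency map
#'
#' A USM pools the gaze of many viewers: the count grids are summed
#' cellwise and then smoothed exactly like an individual map. Because the
#' map is max-normalized, aggregating k identical grids gives the same map
#' as one.
#'
#' @param grids list of [CountGrid-class]s (or count matrices) of one image,
#'   all the same shape.
#' @param ... passed to [smoothToMap()] (`kernelSize`, `sigma`, `normalize`).
#' @return A [SaliencyMap-class] of kind "USM".
#' @export
aggregateUsm <- function(grids, ...) {
  mats <- lapply(grids, function(g) if (is(g, "CountGrid")) gridCounts(g) else as.matrix(g))
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all grids must have the same shape")
  smoothToMap(Reduce(`+`, mats), ..., kind = "USM")
}

## Bilinear resampling of a matrix to a new size (pixel-center alignment).
.bilinear <- function(m, newH, newW) {
  H <- nrow(m); W <- ncol(m)
  sy <- pmin(pmax((seq_len(newH) - 0.5) * H / newH - 0.5, 0), H - 1)
  sx <- pmin(pmax((seq_len(newW) - 0.5) * W / newW - 0.5, 0), W - 1)
  y0 <- pmin(floor(sy), H - 1); y1 <- pmin(y0 + 1, H - 1); fy <- sy - y0
  x0 <- pmin(floor(sx), W - 1); x1 <- pmin(x0 + 1, W - 1); fx <- sx - x0
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - fy, 1 - fx)
  b <- m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - fy, fx)
  cc <- m[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, 1 - fx)
  d <- m[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
  a + b + cc + d
}

#' Resize a saliency map
#'
#' Bilinear resampling followed by re-normalization of measured maps to
#' peak 1 (when nonzero). The reference pipeline compresses stimuli and
#' maps to 1/4 of their size before model training; resizing a smoothed
#' Gaussian bump by factor f scales its SD by f (sigma 24 -> 6 at 1/4).
#'
#' @param map a [SaliencyMap-class].
#' @param factor scale factor (> 0), e.g. 1/4.
#' @return A resized [SaliencyMap-class] of the same kind.
#' @export
resizeMap <- function(map, factor) {
  stopifnot(factor > 0)
  v <- mapValues(map)
  newH <- max(1L, as.integer(round(nrow(v) * factor)))
  newW <- max(1L, as.integer(round(ncol(v) * factor)))
  out <- .bilinear(v, newH, newW)
  out[out < 0] <- 0
  if (mapKind(map) != "predicted" && max(out) > 0) out <- out / max(out)
  SaliencyMap(out, mapKind(map))
}

#' Estimate smoothing sigma from a map by second moments
#'
#' Treats the map as an unnormalized density over pixel centers and returns
#' the square root of the second central moment along one axis. For a map
#' produced by smoothing a single fixation this recovers the Gaussian
#' kernel's SD (slightly shrunk by kernel truncation).
#'
#' @param map a [SaliencyMap-class] or numeric matrix.
#' @param axis "x" (across columns) or "y".
#' @return Estimated SD in pixels.
#' @export
estimateKernelSigma <- function(map, axis = c("x", "y")) {
  axis <- match.arg(axis)
  v <- if (is(map, "SaliencyMap")) mapValues(map) else as.matrix(map)
  marg <- if (axis == "x") colSums(v) else rowSums(v)
  if (sum(marg) == 0) stop("cannot estimate sigma of an all-zero map")
  pos <- seq_along(marg) - 1
  w <- marg / sum(marg)
  mu <- sum(w * pos)
  sqrt(sum(w * (pos - mu)^2))
}
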