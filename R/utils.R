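#' @import methods
#' @importFrom stats rnorm runif fft lm coef sd median quantile
#' @importFrom utils head write.csv read.csv
NULL

# Unit conversion table: every cross-unit factor used by the package lives
# here so the cm/mm/um policy is auditable in one place.
.units <- list(
  mm2_per_cm2 = 100,
  mm_per_cm   = 10,
  um_per_cm   = 1e4
)

#' Convert an RGB array to grayscale luma
#'
#' Standard Rec.601 luma combination of the three channels. A matrix passes
#' through unchanged.
#'
#' @param img numeric matrix (already gray) or H x W x 3 array in [0, 1].
#' @return numeric matrix in [0, 1].
#' @export
toGray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Otsu threshold of a numeric vector
#'
#' Thin wrapper around \code{EBImage::otsu} operating on a plain vector of
#' values in [0, 1] (EBImage's implementation expects an image).
#'
#' @param v numeric vector in [0, 1].
#' @param levels number of histogram levels.
#' @return scalar threshold.
#' @keywords internal
otsuVector <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) < 2L || diff(range(v)) < .Machine$double.eps) {
    return(if (length(v)) max(v) else 0)
  }
  EBImage::otsu(EBImage::Image(clamp01(v), dim = c(length(v), 1L)),
                range = c(0, 1), levels = levels)
}

# 1-D Gaussian and its first/second derivatives, sampled on integer
# offsets. Discrete moments are corrected so that a constant image has
# exactly zero derivative response (truncated continuous kernels do not
# sum to their continuous moments).
gaussKernel1d <- function(sigma, order = 0L, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  switch(as.character(order),
         "0" = g / sum(g),
         "1" = { k <- -x / sigma^2 * g; k - mean(k) },
         "2" = { k <- (x^2 - sigma^2) / sigma^4 * g; k - mean(k) },
         stop("order must be 0, 1 or 2"))
}

# 2-D convolution with replicated borders via EBImage (FFT-based). Images
# smaller than the kernel are replicate-padded first.
convolve2d <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  pr <- max(0L, nrow(kernel) - h); pc <- max(0L, ncol(kernel) - w)
  if (pr > 0L || pc > 0L) {
    ri <- c(rep(1L, ceiling(pr / 2)), seq_len(h), rep(h, floor(pr / 2) + 1L))
    ci <- c(rep(1L, ceiling(pc / 2)), seq_len(w), rep(w, floor(pc / 2) + 1L))
    padded <- img[ri, ci, drop = FALSE]
    out <- EBImage::imageData(EBImage::filter2(EBImage::Image(padded),
                                               kernel,
                                               boundary = "replicate"))
    return(out[ceiling(pr / 2) + seq_len(h), ceiling(pc / 2) + seq_len(w),
               drop = FALSE])
  }
  EBImage::imageData(EBImage::filter2(EBImage::Image(img), kernel,
                                      boundary = "replicate"))
}

#' Gaussian blur of a matrix
#' @keywords internal
blurGray <- function(img, sigma) {
  if (sigma <= 0) return(img)
  g <- gaussKernel1d(sigma)
  convolve2d(img, outer(g, g))
}

# Disc / diamond structuring elements (odd-sized, radius r).
brushDisc <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
brushDiamond <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "diamond")

# Binary morphology on logical/0-1 matrices, returning logical.
erodeMask  <- function(m, brush) as.matrix(EBImage::erode(m * 1, brush)) > 0.5
dilateMask <- function(m, brush) as.matrix(EBImage::dilate(m * 1, brush)) > 0.5

# Drop connected components below an absolute pixel area (8-connected).
dropSmallComponents <- function(mask, minArea) {
  if (!any(mask) || minArea <= 1) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  areas <- tabulate(as.integer(lab[lab > 0]))
  keep <- which(areas >= minArea)
  matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
}

# Bilinear sampling of a matrix at fractional (x = col, y = row) positions.
# Out-of-range samples return NA.
bilinearSample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  ok <- x >= 1 & y >= 1 & x <= w & y <= h
  # clamp indices so vector indexing stays legal; invalid results masked
  # after. The clamp also makes samples exactly on the far edge valid.
  x0 <- pmin(pmax(floor(x), 1), w - 1); y0 <- pmin(pmax(floor(y), 1), h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * h + y0
  v <- (1 - fx) * (1 - fy) * img[i00] +
       fx * (1 - fy) * img[i00 + h] +
       (1 - fx) * fy * img[i00 + 1] +
       fx * fy * img[i00 + h + 1]
  v[!ok] <- NA_real_
  v
}

# Nearest-neighbour sampling (used for depth, where interpolation would
# invent geometry).
nearestSample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  xi <- round(x); yi <- round(y)
  ok <- xi >= 1 & yi >= 1 & xi <= w & yi <= h
  xi <- pmin(pmax(xi, 1), w); yi <- pmin(pmax(yi, 1), h)
  v <- img[(xi - 1) * h + yi]
  v[!ok] <- NA_real_
  v
}

withSeedIfGiven <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
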