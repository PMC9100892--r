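# Planar projective geometry: the glue between views. Homographies are
# 3 x 3 matrices acting on homogeneous (x = col, y = row, 1) coordinates,
# normalized so H[3, 3] == 1.

#' Normalize a homography
#'
#' Scales a 3 x 3 projective matrix so its bottom-right entry equals 1.
#'
#' @param H 3 x 3 matrix with nonzero \code{H[3, 3]}.
#' @return normalized 3 x 3 matrix.
#' @export
normalizeHomography <- function(H) {
  stopifnot(is.matrix(H), all(dim(H) == 3L))
  if (abs(H[3, 3]) < 1e-14) stop("H[3,3] ~ 0; cannot normalize")
  H / H[3, 3]
}

#' Apply a homography to points
#'
#' @param H 3 x 3 homography.
#' @param xy n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
applyHomography <- function(H, xy) {
  xy <- matrix(xy, ncol = 2L)
  p <- cbind(xy, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

# Direct linear transform with Hartley normalization. pts* are n x 2.
dltHomography <- function(src, dst) {
  n <- nrow(src)
  stopifnot(n >= 4L, nrow(dst) == n)
  normT <- function(p) {
    mu <- colMeans(p)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    if (!is.finite(s) || s <= 0) s <- 1
    rbind(c(s, 0, -s * mu[1]), c(0, s, -s * mu[2]), c(0, 0, 1))
  }
  Ts <- normT(src); Td <- normT(dst)
  s <- applyHomography(Ts, src); d <- applyHomography(Td, dst)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-s[, 1], -s[, 2], -1, 0, 0, 0,
                                 d[, 1] * s[, 1], d[, 1] * s[, 2], d[, 1])
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -s[, 1], -s[, 2], -1,
                                 d[, 2] * s[, 1], d[, 2] * s[, 2], d[, 2])
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- solve(Td) %*% matrix(h, 3, 3, byrow = TRUE) %*% Ts
  normalizeHomography(H)
}

#' Warp an image by a homography
#'
#' Resamples \code{img} onto an output canvas so that output pixel
#' (x + offset[1], y + offset[2]) carries the value of the source at
#' \code{solve(H) \%*\% (x, y, 1)}: \code{H} maps source coordinates into
#' the canvas plane. Colour uses bilinear interpolation; depth should use
#' \code{interp = "nearest"} so no geometry is invented between pixels.
#'
#' @param img matrix or H x W x 3 array.
#' @param H homography mapping source pixels into the canvas plane.
#' @param size output c(H, W).
#' @param offset canvas coordinate of the output's (0, 0) corner, c(x, y);
#'   output pixel (col j, row i) has canvas coordinates (j + x, i + y).
#' @param interp "bilinear" or "nearest".
#' @return warped image of dimension \code{size} (plus channels), NA outside
#'   the source footprint.
#' @export
warpImage <- function(img, H, size, offset = c(0, 0),
                      interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  Hh <- size[1]; Ww <- size[2]
  grid <- cbind(x = rep(seq_len(Ww), each = Hh) + offset[1],
                y = rep(seq_len(Hh), times = Ww) + offset[2])
  src <- applyHomography(solve(H), grid)
  sampler <- if (interp == "bilinear") bilinearSample else nearestSample
  warpOne <- function(m) matrix(sampler(m, src[, 1], src[, 2]), Hh, Ww)
  if (is.matrix(img)) return(warpOne(img))
  out <- array(NA_real_, c(Hh, Ww, dim(img)[3]))
  for (k in seq_len(dim(img)[3])) out[, , k] <- warpOne(img[, , k])
  out
}
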