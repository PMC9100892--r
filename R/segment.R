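# Multi-scale Hessian vesselness segmentation of tubular bright roots.
#
# At each scale sigma the image is smoothed by convolution with Gaussian
# derivative kernels and the scale-normalized (sigma^2) Hessian is
# eigendecomposed in closed form, ordering |lambda1| <= |lambda2|. The
# per-pixel tubularity response combines the eccentricity ratio
# RB = |lambda1| / |lambda2| and the structureness S (Frobenius norm of the
# Hessian), suppressing pixels with lambda2 > 0 (bright tubes on a dark
# substrate); the multi-scale response is the pointwise maximum over scales.

#' Vesselness filter parameters
#'
#' @param sigmaMin,sigmaMax scale range, px (0.5 <= sigmaMin <= sigmaMax).
#' @param nScales number of geometrically spaced scales.
#' @param beta eccentricity sensitivity, in [0.3, 2].
#' @param c structureness sensitivity, positive number, or \code{"auto"}
#'   (half the maximum structureness at each scale - the standard choice;
#'   an explicit value is passed through verbatim).
#' @return a validated parameter list of class \code{VesselnessParams}.
#' @export
vesselnessParams <- function(sigmaMin = 1, sigmaMax = 8, nScales = 6L,
                             beta = 0.5, c = "auto") {
  stopifnot(sigmaMin > 0, sigmaMin <= sigmaMax, nScales >= 1L)
  if (beta < 0.3 || beta > 2) stop("beta must lie in [0.3, 2]")
  if (!identical(c, "auto")) stopifnot(is.numeric(c), c > 0)
  structure(list(sigmaMin = sigmaMin, sigmaMax = sigmaMax,
                 nScales = as.integer(nScales), beta = beta, c = c),
            class = "VesselnessParams")
}

#' Scale-normalized Hessian eigenvalues of an image
#'
#' Convolves with sigma-scaled Gaussian second-derivative kernels,
#' multiplies by sigma^2 (scale-space normalization, so responses are
#' comparable across scales), and eigendecomposes the symmetric 2 x 2
#' Hessian per pixel in closed form.
#'
#' @param gray matrix.
#' @param sigma Gaussian scale, px (>= 0.5).
#' @param polarity "bright" tubes (default) or "dark" (image is inverted).
#' @return list with matrices \code{lambda1}, \code{lambda2}
#'   (|lambda1| <= |lambda2|), and \code{sigma}.
#' @export
hessianEigen <- function(gray, sigma, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  stopifnot(sigma >= 0.5)
  if (polarity == "dark") gray <- max(gray) - gray
  g0 <- gaussKernel1d(sigma, 0L); g2 <- gaussKernel1d(sigma, 2L)
  g1 <- gaussKernel1d(sigma, 1L)
  s2 <- sigma^2
  ixx <- s2 * convolve2d(gray, outer(g0, g2))  # d^2/dx^2 (x = col)
  iyy <- s2 * convolve2d(gray, outer(g2, g0))
  ixy <- s2 * convolve2d(gray, outer(g1, g1))
  tr <- (ixx + iyy) / 2
  dd <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  ea <- tr + dd; eb <- tr - dd
  swap <- abs(ea) > abs(eb)
  l1 <- ifelse(swap, eb, ea)
  l2 <- ifelse(swap, ea, eb)
  list(lambda1 = l1, lambda2 = l2, sigma = sigma)
}

#' Single-scale vesselness response
#'
#' V = 0 where lambda2 > 0, else
#' exp(-RB^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2))), with
#' RB = |lambda1| / |lambda2| (0 at flat pixels where lambda2 = 0) and
#' S = sqrt(lambda1^2 + lambda2^2).
#'
#' @param field output of \code{\link{hessianEigen}}.
#' @param beta eccentricity sensitivity (> 0).
#' @param c structureness sensitivity, or \code{"auto"} for half the
#'   maximum S over the field.
#' @return matrix of responses in [0, 1].
#' @export
vesselnessSingleScale <- function(field, beta = 0.5, c = "auto") {
  if (beta <= 0) stop("beta must be > 0")
  l1 <- field$lambda1; l2 <- field$lambda2
  S <- sqrt(l1^2 + l2^2)
  if (identical(c, "auto")) {
    c <- max(S) / 2
    if (c <= 0) return(matrix(0, nrow(l1), ncol(l1)))
  }
  rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * c^2)))
  v[l2 > 0] <- 0
  v
}

#' Multi-scale vesselness map
#'
#' Pointwise maximum of the single-scale responses over a geometric scale
#' ladder; the scale winning at each pixel (the one matching the local tube
#' width) is recorded.
#'
#' @param gray matrix in [0, 1].
#' @param params \code{\link{vesselnessParams}}.
#' @param polarity "bright" or "dark" tubes.
#' @return list with \code{v} (responses in [0, 1]), \code{scale} (winning
#'   sigma per pixel), \code{scales} (the ladder).
#' @export
multiscaleVesselness <- function(gray, params = vesselnessParams(),
                                 polarity = "bright") {
  sc <- if (params$nScales == 1L) params$sigmaMin
        else exp(seq(log(params$sigmaMin), log(params$sigmaMax),
                     length.out = params$nScales))
  v <- matrix(0, nrow(gray), ncol(gray))
  win <- matrix(sc[1], nrow(gray), ncol(gray))
  for (s in sc) {
    vs <- vesselnessSingleScale(hessianEigen(gray, s, polarity),
                                beta = params$beta, c = params$c)
    better <- vs > v
    win[better] <- s
    v[better] <- vs[better]
  }
  list(v = v, scale = win, scales = sc)
}

#' Binarize a vesselness map into a root mask
#'
#' Thresholds the response (Otsu restricted to the foreground by default,
#' or a fixed value), intersects with the foreground mask, and removes
#' small components.
#'
#' @param vmap vesselness list from \code{\link{multiscaleVesselness}} or a
#'   response matrix.
#' @param foreground logical matrix limiting the root-ball region (NULL =
#'   whole image).
#' @param threshold \code{"otsu"} or a fixed value in [0, 1].
#' @param minArea components below this pixel area are dropped.
#' @param hysteresisLow optional fraction in (0, 1): keep pixels above
#'   \code{hysteresisLow * threshold} whose connected component touches the
#'   high threshold. The high threshold alone marks tube cores; hysteresis
#'   recovers the full tube width without admitting detached background
#'   speckle.
#' @return logical root mask, a subset of \code{foreground}; an all-zero
#'   response yields an empty mask with a warning.
#' @export
binarizeMask <- function(vmap, foreground = NULL, threshold = "otsu",
                         minArea = 30L, hysteresisLow = NULL) {
  v <- if (is.list(vmap)) vmap$v else vmap
  if (is.null(foreground)) foreground <- matrix(TRUE, nrow(v), ncol(v))
  if (max(v[foreground]) <= 0) {
    warning("all-zero vesselness response: empty root mask")
    return(matrix(FALSE, nrow(v), ncol(v)))
  }
  thr <- if (identical(threshold, "otsu")) otsuVector(v[foreground])
         else as.numeric(threshold)
  mask <- v > thr & foreground
  if (!is.null(hysteresisLow) && any(mask)) {
    lab <- EBImage::bwlabel((v > hysteresisLow * thr & foreground) * 1)
    keep <- unique(lab[mask & lab > 0])
    mask <- matrix(as.integer(lab) %in% keep, nrow(v), ncol(v))
  }
  dropSmallComponents(mask, minArea)
}

#' Refine a root mask against the intensity image
#'
#' Vesselness localizes tubes but its support does not coincide with the
#' photometric tube boundary (a halo for thin tubes, a shrunken core for
#' wide ones). This step re-delineates the width: within a small dilation
#' of the detected mask, pixels brighter than the local Otsu threshold are
#' kept, placing the boundary at the bright/dark transition of the roots
#' themselves.
#'
#' @param mask logical mask of detected tubes.
#' @param gray intensity image the boundary is read from (typically the
#'   illumination-corrected image that fed the vesselness filter).
#' @param dilateR how far (px) beyond the detected mask the boundary may
#'   move outward.
#' @param minArea components below this pixel area are dropped.
#' @return refined logical mask.
#' @export
refineRootMask <- function(mask, gray, dilateR = 2L, minArea = 30L) {
  if (!any(mask)) return(mask)
  region <- dilateMask(mask, brushDisc(dilateR))
  thr <- otsuVector(gray[region])
  dropSmallComponents(region & gray > thr, minArea)
}
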