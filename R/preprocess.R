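# Image preprocessing ahead of segmentation: contrast enhancement,
# edge-based background (root-ball) extraction, homomorphic illumination
# correction.

#' Brightness gain and gamma contrast enhancement
#'
#' Multiplies intensities by \code{gain}, clips to [0, 1], then applies a
#' power-law (gamma) transform per channel.
#'
#' @param img gray matrix or RGB array in [0, 1].
#' @param gain multiplicative light-intensity gain.
#' @param gamma power-law exponent (> 0); values < 1 brighten mid-tones.
#' @return enhanced image, same shape.
#' @export
enhance <- function(img, gain = 1.4, gamma = 0.8) {
  if (gamma <= 0) stop("gamma must be > 0")
  clamp01(gain * img)^gamma
}

#' Edge-based background removal
#'
#' Extracts the root-ball (foreground) region: Sobel gradient magnitude,
#' threshold (Otsu by default), dilation with a disk, morphological hole
#' filling, erosion with a diamond, opening with a disk, then a
#' connected-component filter that keeps components whose area is at least
#' half the largest component's area (configurably, a fraction of the whole
#' image instead). The root ball is the big textured blob; the smooth or
#' weakly textured surround falls away.
#'
#' @param img gray matrix or RGB array in [0, 1].
#' @param sobelThreshold gradient-magnitude threshold in [0, 1] of the
#'   normalized magnitude, or \code{"otsu"}.
#' @param dilateR disk radius for edge dilation, px.
#' @param erodeR diamond radius for erosion, px.
#' @param openR disk radius for the final opening, px.
#' @param scaleToWidth reference width the default radii are stated at;
#'   radii are scaled linearly with \code{ncol(img) / scaleToWidth}.
#' @param componentRule "half-largest" (default) keeps components with
#'   area >= half the largest component; "image-fraction" keeps components
#'   >= \code{imageFraction} of all pixels.
#' @param imageFraction fraction for the "image-fraction" rule.
#' @return list with \code{mask} (logical foreground) and \code{masked}
#'   (input with background zeroed); raises a \code{noForeground} condition
#'   if nothing survives.
#' @export
removeBackground <- function(img, sobelThreshold = "otsu", dilateR = 10L,
                             erodeR = 3L, openR = 3L, scaleToWidth = 1280L,
                             componentRule = c("half-largest",
                                               "image-fraction"),
                             imageFraction = 0.1) {
  componentRule <- match.arg(componentRule)
  gray <- toGray(img)
  sc <- ncol(gray) / scaleToWidth
  rad <- function(r) max(1L, as.integer(round(r * sc)))
  gx <- convolve2d(gray, sobelX); gy <- convolve2d(gray, sobelY)
  mag <- sqrt(gx^2 + gy^2)
  fail0 <- function() stop(structure(class = c("noForeground", "error",
                                               "condition"),
    list(message = "no foreground region survives background removal",
         call = sys.call(-1))))
  if (max(mag) < 1e-8) fail0()  # featureless image (FFT noise floor)
  mag <- mag / max(mag)
  thr <- if (identical(sobelThreshold, "otsu")) otsuVector(mag)
         else as.numeric(sobelThreshold)
  edges <- mag > thr
  fail <- function() stop(structure(class = c("noForeground", "error",
                                              "condition"),
    list(message = "no foreground region survives background removal",
         call = sys.call(-1))))
  if (!any(edges)) fail()
  m <- dilateMask(edges, brushDisc(rad(dilateR)))
  m <- as.matrix(EBImage::fillHull(m * 1)) > 0.5
  m <- erodeMask(m, brushDiamond(rad(erodeR)))
  m <- dilateMask(erodeMask(m, brushDisc(rad(openR))), brushDisc(rad(openR)))
  if (!any(m)) fail()
  lab <- EBImage::bwlabel(m * 1)
  areas <- tabulate(as.integer(lab[lab > 0]))
  minArea <- if (componentRule == "half-largest") max(areas) / 2
             else imageFraction * length(gray)
  keep <- which(areas >= minArea)
  mask <- matrix(as.integer(lab) %in% keep, nrow(gray), ncol(gray))
  if (!any(mask)) fail()
  masked <- if (is.matrix(img)) img * mask
            else array(as.vector(img) * as.vector(mask), dim(img))
  list(mask = mask, masked = masked)
}

#' Homomorphic illumination correction
#'
#' Separates illumination from reflectance in the log domain: log(1 + x),
#' 2-D FFT, a Gaussian high-emphasis gain
#' \code{gammaL + (gammaH - gammaL) * (1 - exp(-D^2 / (2 d0^2)))} over the
#' centred frequency radius D, inverse FFT, exp, then a min-max rescale to
#' [0, 1] (guarded: a constant image stays constant). With
#' \code{gammaH = gammaL = 1} the filter is an exact all-pass.
#'
#' @param gray matrix in [0, 1].
#' @param gammaH high-frequency gain (>= gammaL).
#' @param gammaL low-frequency gain (> 0).
#' @param d0 Gaussian cutoff in frequency-index units; default
#'   \code{0.05 * min(dim(gray))}.
#' @return filtered matrix in [0, 1].
#' @export
homomorphicFilter <- function(gray, gammaH = 1.5, gammaL = 0.5, d0 = NULL) {
  stopifnot(is.matrix(gray))
  if (any(!is.finite(gray))) stop("non-finite values in input")
  if (gammaL <= 0 || gammaH < gammaL)
    stop("need gammaH >= gammaL > 0")
  h <- nrow(gray); w <- ncol(gray)
  if (is.null(d0)) d0 <- 0.05 * min(h, w)
  lg <- log1p(gray)
  F <- fft(lg)
  fr <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1))
  fc <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1))
  D2 <- outer(fr^2, fc^2, "+")
  gain <- gammaL + (gammaH - gammaL) * (1 - exp(-D2 / (2 * d0^2)))
  out <- expm1(Re(fft(F * gain, inverse = TRUE)) / (h * w))
  rng <- range(out)
  if (diff(rng) < 1e-12) return(clamp01(out))
  (out - rng[1]) / diff(rng)
}
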