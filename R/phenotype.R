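# Phenotype measurement and prediction: depth-based pixel calibration,
# non-overlapping-root extraction, skeleton length, average diameter,
# encapsulation, and the allometric total-root predictions.

#' Calibrate physical pixel scale from the depth point cloud
#'
#' Back-projects every ROI pixel to 3-D through the pinhole model, sums the
#' per-pixel surface patch areas (norm of the cross product of the two
#' local tangent vectors, from central differences of the 3-D coordinate
#' grids), and derives the mean per-pixel area S_pix = S_ROI / n and pixel
#' length L_pix = sqrt(S_pix). Invalid (zero) depth pixels are infilled
#' from their nearest valid neighbours before differentiation; optionally
#' the depth is Gaussian-smoothed first (recommended for quantized
#' integer-millimetre depth).
#'
#' @param depth matrix, mm (0 = invalid).
#' @param intr named vector fx, fy, cx, cy (pixels).
#' @param roiMask logical matrix selecting the ROI (NULL = whole grid).
#' @param smoothSigma Gaussian sd (px) applied to the depth before
#'   differentiation; 0 disables smoothing (default, exact for synthetic
#'   float depth).
#' @return a \linkS4class{CalibrationResult}.
#' @export
calibrate <- function(depth, intr, roiMask = NULL, smoothSigma = 0) {
  if (is.null(roiMask)) roiMask <- matrix(TRUE, nrow(depth), ncol(depth))
  valid <- depth > 0
  if (!any(valid & roiMask)) stop("no valid depth pixels in the ROI")
  z <- depth
  if (!all(valid)) {
    # nearest-neighbour infill by iterative 3 x 3 averaging of valid pixels
    while (any(z == 0)) {
      zi <- EBImage::Image(z)
      s <- as.matrix(EBImage::filter2(zi, matrix(1, 3, 3) / 9,
                                      boundary = "replicate"))
      n <- as.matrix(EBImage::filter2(EBImage::Image((z > 0) * 1),
                                      matrix(1, 3, 3) / 9,
                                      boundary = "replicate"))
      fill <- z == 0 & n > 1e-9
      if (!any(fill)) stop("depth infill failed: isolated invalid region")
      z[fill] <- s[fill] / n[fill]
    }
  }
  if (smoothSigma > 0) z <- blurGray(z, smoothSigma)
  h <- nrow(z); w <- ncol(z)
  X <- sweep(z, 2, (seq_len(w) - intr["cx"]) / intr["fx"], "*")
  Y <- sweep(z, 1, (seq_len(h) - intr["cy"]) / intr["fy"], "*")
  dcol <- function(M) {  # derivative along columns (x direction)
    d <- M
    d[, 2:(w - 1)] <- (M[, 3:w] - M[, 1:(w - 2)]) / 2
    d[, 1] <- M[, 2] - M[, 1]; d[, w] <- M[, w] - M[, w - 1]
    d
  }
  drow <- function(M) {
    d <- M
    d[2:(h - 1), ] <- (M[3:h, ] - M[1:(h - 2), ]) / 2
    d[1, ] <- M[2, ] - M[1, ]; d[h, ] <- M[h, ] - M[h - 1, ]
    d
  }
  xu <- dcol(X); yu <- dcol(Y); zu <- dcol(z)
  xv <- drow(X); yv <- drow(Y); zv <- drow(z)
  cx1 <- yu * zv - zu * yv
  cx2 <- zu * xv - xu * zv
  cx3 <- xu * yv - yu * xv
  areaMM2 <- sqrt(cx1^2 + cx2^2 + cx3^2)
  sROI <- sum(areaMM2[roiMask]) / .units$mm2_per_cm2
  calibrationResult(sROI, sum(roiMask))
}

#' Extract non-overlapping roots from a root mask
#'
#' Single (non-overlapping) roots vanish under erosion and therefore
#' cannot be restored by the subsequent dilation, while overlap regions
#' survive and are restored; subtracting the restored image from the mask
#' leaves the non-overlapping roots: erode (disk) -> median filter ->
#' dilate (disk) -> mask AND NOT restored.
#'
#' @param mask logical root mask.
#' @param erosionR disk erosion radius, px; must exceed the thickest single
#'   root's half-width for the overlap logic to apply.
#' @param medianK median filter window (odd), px.
#' @param dilationR disk dilation radius; defaults to \code{erosionR}
#'   (restoration symmetry).
#' @return logical mask of non-overlapping roots.
#' @export
extractNonoverlapping <- function(mask, erosionR = 2L, medianK = 3L,
                                  dilationR = erosionR) {
  if (!any(mask)) return(mask & FALSE)
  er <- erodeMask(mask, brushDisc(erosionR))
  if (any(er)) {
    med <- as.matrix(EBImage::medianFilter(EBImage::Image(er * 1),
                                           (medianK - 1L) %/% 2L)) > 0.5
    restored <- dilateMask(med, brushDisc(dilationR))
  } else restored <- er
  mask & !restored
}

#' Calibrated skeleton length of a root mask
#'
#' Thins the mask to a one-pixel skeleton and converts the pixel count to
#' physical length as count x 1.2 x L_pix: the 1.2 factor is the average
#' of the pixel edge length and the pixel diagonal, compensating for the
#' mix of straight and diagonal skeleton steps. The Euclidean 8-connected
#' chain length (edges x 1, diagonals x sqrt(2)) is reported alongside for
#' comparison.
#'
#' @param mask logical mask (typically non-overlapping roots).
#' @param cal a \linkS4class{CalibrationResult}.
#' @param smooth median-filter (3 x 3) the mask before thinning; regularizes
#'   ragged segmentation boundaries that would otherwise spawn skeleton
#'   artifacts. Leave FALSE when the input is already a thin structure (a
#'   3 x 3 median erases one-pixel lines).
#' @return list with \code{lengthCm}, \code{skeleton} (logical matrix),
#'   \code{nPixels}, and \code{euclideanCm}.
#' @export
skeletonLength <- function(mask, cal, smooth = FALSE) {
  if (smooth)
    mask <- as.matrix(EBImage::medianFilter(EBImage::Image(mask * 1),
                                            1L)) > 0.5
  skel <- thinMask(mask)
  n <- sum(skel)
  lp <- pixelLength(cal)
  # Euclidean chain length: each 8-neighbour link contributes half its
  # length to both endpoints
  s <- matrix(0L, nrow(skel) + 2L, ncol(skel) + 2L)
  s[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)] <- as.integer(skel)
  lk <- function(di, dj) sum(s[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)] &
                             s[2:(nrow(skel) + 1L) + di,
                               2:(ncol(skel) + 1L) + dj])
  euclid <- (lk(0L, 1L) + lk(1L, 0L)) * lp +
            (lk(1L, 1L) + lk(1L, -1L)) * sqrt(2) * lp
  list(lengthCm = n * 1.2 * lp, skeleton = skel, nPixels = n,
       euclideanCm = euclid)
}

#' Average root diameter from non-overlapping roots
#'
#' The mean diameter is the ratio of the non-overlapping-root surface area
#' (S_pix x pixel count) to the skeleton length, converted to micrometres.
#'
#' @param mask logical non-overlapping-root mask.
#' @param skelLengthCm calibrated skeleton length, cm.
#' @param cal a \linkS4class{CalibrationResult}.
#' @return list with \code{sasrNoCm2}, \code{lengthCm}, \code{adtrUm};
#'   raises an \code{undefinedDiameter} condition on a zero-length
#'   skeleton.
#' @export
averageDiameter <- function(mask, skelLengthCm, cal) {
  if (skelLengthCm <= 0)
    stop(structure(class = c("undefinedDiameter", "error", "condition"),
      list(message = "zero skeleton length: diameter undefined",
           call = sys.call(-1))))
  sasrNo <- pixelArea(cal) * sum(mask)
  list(sasrNoCm2 = sasrNo, lengthCm = skelLengthCm,
       adtrUm = sasrNo / skelLengthCm * .units$um_per_cm)
}

#' Root encapsulation (density of surface root)
#'
#' Percentage of the soil-matrix surface covered by root pixels:
#' DSR = 100 x |root| / |matrix|, with the matrix taken as the union of
#' the foreground and root masks.
#'
#' @param rootMask logical surface-root mask.
#' @param matrixMask logical soil-matrix (foreground) mask.
#' @return list with \code{dsr} (percent), \code{pixRoot}, \code{pixAll}.
#' @export
encapsulation <- function(rootMask, matrixMask) {
  all <- matrixMask | rootMask
  if (!any(all)) stop("empty matrix mask")
  list(dsr = 100 * sum(rootMask) / sum(all),
       pixRoot = sum(rootMask), pixAll = sum(all))
}

#' Reference allometric prediction models
#'
#' Slope/intercept of the univariate linear models shipped with the
#' package, fitted on pumpkin rootstock plug seedlings: \code{"satr"}
#' predicts total-root surface area (cm^2) from surface-root surface area,
#' \code{"ltr"} predicts total-root length (cm) from the calculated
#' length.
#'
#' @param which \code{"satr"} or \code{"ltr"}.
#' @return a \linkS4class{PredictionModel}.
#' @export
referenceModel <- function(which = c("satr", "ltr")) {
  which <- match.arg(which)
  switch(which,
         satr = predictionModel(2.16556, 7.6522),
         ltr  = predictionModel(2.9723, 16.83062))
}

#' Predict total-root surface area
#'
#' SATR = slope x SASR + intercept.
#'
#' @param sasr surface-root surface area, cm^2 (>= 0).
#' @param model a \linkS4class{PredictionModel}; default the shipped model.
#' @return predicted total-root surface area, cm^2.
#' @export
predictTotalSurfaceArea <- function(sasr, model = referenceModel("satr")) {
  stopifnot(all(sasr >= 0))
  model@slope * sasr + model@intercept
}

#' Predict total-root length
#'
#' LTR = SATRP / ADTR (diameter converted to cm), then
#' LTRP = slope x LTR + intercept.
#'
#' @param satrp predicted total-root surface area, cm^2.
#' @param adtrUm average diameter, um (> 0).
#' @param model a \linkS4class{PredictionModel}; default the shipped model.
#' @return named vector c(ltr, ltrp), cm.
#' @export
predictTotalLength <- function(satrp, adtrUm, model = referenceModel("ltr")) {
  if (any(adtrUm <= 0)) stop("adtrUm must be > 0")
  ltr <- satrp / (adtrUm / .units$um_per_cm)
  c(ltr = ltr, ltrp = model@slope * ltr + model@intercept)
}

#' Total-root volume
#'
#' Cylinder model: VTR = pi (ADTR / 2)^2 x LTRP in consistent cm units.
#'
#' @param adtrUm average diameter, um.
#' @param ltrpCm predicted total-root length, cm.
#' @return volume, cm^3.
#' @export
totalVolume <- function(adtrUm, ltrpCm) {
  stopifnot(all(adtrUm >= 0), all(ltrpCm >= 0))
  pi * (adtrUm / .units$um_per_cm / 2)^2 * ltrpCm
}

#' Fit a univariate prediction model by ordinary least squares
#'
#' @param x,y paired samples (n >= 3, x not constant).
#' @return a \linkS4class{PredictionModel} with nFit and r^2 filled in.
#' @export
fitPredictionModel <- function(x, y) {
  if (length(x) < 3L || length(y) != length(x))
    stop("need n >= 3 paired samples")
  if (sd(x) < 1e-12) stop("x is constant; slope undefined")
  fit <- lm(y ~ x)
  # summary.lm warns on exact fits; r^2 = 1 is a legitimate answer here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  predictionModel(unname(coef(fit)[2]), unname(coef(fit)[1]),
                  nFit = length(x), r2 = r2)
}

#' Assemble a phenotype report
#'
#' Combines all measured and predicted quantities into a validated
#' \linkS4class{PhenotypeReport}; the cylinder-volume consistency
#' invariant is re-checked by the class validity method.
#'
#' @param plantId identifier.
#' @param adtrUm average diameter of total root, um.
#' @param sasrCm2 surface area of surface root, cm^2.
#' @param dsrPct encapsulation, percent.
#' @param saCm2 surface soil area, cm^2.
#' @param satrpCm2 predicted total-root surface area, cm^2.
#' @param ltrCm,ltrpCm calculated / predicted total-root length, cm.
#' @param vtrCm3 total-root volume, cm^3.
#' @return a \linkS4class{PhenotypeReport}.
#' @export
assembleReport <- function(plantId, adtrUm, sasrCm2, dsrPct, saCm2,
                           satrpCm2, ltrCm, ltrpCm, vtrCm3) {
  args <- list(adtrUm = adtrUm, sasrCm2 = sasrCm2, dsrPct = dsrPct,
               saCm2 = saCm2, satrpCm2 = satrpCm2, ltrCm = ltrCm,
               ltrpCm = ltrpCm, vtrCm3 = vtrCm3)
  miss <- names(args)[!vapply(args, function(a)
    length(a) == 1L && is.finite(a), logical(1))]
  if (length(miss))
    stop("missing or non-finite phenotype field(s): ",
         paste(miss, collapse = ", "))
  new("PhenotypeReport", plantId = as.character(plantId), adtr = adtrUm,
      sasr = sasrCm2, dsr = dsrPct, sa = saCm2, satrp = satrpCm2,
      ltr = ltrCm, ltrp = ltrpCm, vtr = vtrCm3)
}
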