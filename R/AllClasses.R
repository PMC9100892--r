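#' RGBDFrame: one co-registered colour + depth view
#'
#' Container for a single camera view: an 8-bit-equivalent colour image
#' (stored as numeric in [0, 1]), a depth map in millimetres (0 marks invalid
#' pixels), and the pinhole intrinsics of the camera. Colour and depth must
#' share the pixel grid (the vendor alignment step is assumed to have been
#' applied upstream; see \code{\link{alignDepth}}).
#'
#' @slot color numeric H x W x 3 array in [0, 1].
#' @slot depth numeric H x W matrix, millimetres; 0 = invalid.
#' @slot intrinsics named numeric vector \code{fx, fy, cx, cy} in pixels.
#' @export
setClass("RGBDFrame",
  representation(color = "array", depth = "matrix", intrinsics = "numeric"))

setValidity("RGBDFrame", function(object) {
  dc <- dim(object@color)
  if (length(dc) != 3L || dc[3] != 3L)
    return("color must be an H x W x 3 array")
  if (!identical(dc[1:2], dim(object@depth)))
    return("color and depth must share the same H x W grid")
  if (any(object@depth < 0, na.rm = TRUE))
    return("depth must be non-negative (0 = invalid)")
  need <- c("fx", "fy", "cx", "cy")
  if (!all(need %in% names(object@intrinsics)))
    return("intrinsics must contain fx, fy, cx, cy")
  TRUE
})

#' Construct an RGBDFrame
#'
#' @param color H x W x 3 array in [0, 1] (a gray matrix is replicated).
#' @param depth H x W depth matrix in millimetres, 0 = invalid.
#' @param intrinsics named numeric vector with \code{fx, fy, cx, cy} (pixels).
#' @return an \linkS4class{RGBDFrame}.
#' @export
RGBDFrame <- function(color, depth, intrinsics) {
  if (is.matrix(color)) color <- array(color, c(dim(color), 3L))
  new("RGBDFrame", color = color, depth = depth,
      intrinsics = intrinsics[c("fx", "fy", "cx", "cy")])
}

#' SceneSpec: parameters of a synthetic root-ball scene
#'
#' Describes the simulated capture: canvas size, root population, fiducial
#' cell size, substrate texture, and the cylindrical depth model of the
#' plug (radius + axis distance, viewed through a pinhole of focal length
#' \code{focal}). Defaults are the package's reference study conditions.
#'
#' @slot imageSize integer c(H, W) of the panorama, pixels.
#' @slot nRoots number of surface roots.
#' @slot widthRange numeric c(min, max) root width, pixels.
#' @slot rootIntensity peak root brightness in [0, 1].
#' @slot speckleDensity fraction of substrate pixels carrying bright speckle.
#' @slot fiducialCell fiducial block edge, pixels (>= 4).
#' @slot bandHeight height of the root-ball band, pixels.
#' @slot cylinderRadius root-ball (plug) radius, mm.
#' @slot axisDistance camera-to-cylinder-axis distance, mm.
#' @slot backgroundDepth fiducial curtain depth, mm.
#' @slot focal pinhole focal length, pixels (fx = fy).
#' @slot seed integer RNG seed; a fixed seed gives byte-identical scenes.
#' @export
setClass("SceneSpec",
  representation(imageSize = "integer", nRoots = "integer",
                 widthRange = "numeric", rootIntensity = "numeric",
                 speckleDensity = "numeric", fiducialCell = "integer",
                 bandHeight = "integer", cylinderRadius = "numeric",
                 axisDistance = "numeric", backgroundDepth = "numeric",
                 focal = "numeric", seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (object@widthRange[1] < 1) return("widthRange min must be >= 1 px")
  if (object@nRoots < 0) return("nRoots must be >= 0")
  if (object@fiducialCell < 4) return("fiducialCell must be >= 4 px")
  if (any(object@fiducialCell > object@imageSize))
    return("fiducialCell larger than the image")
  if (object@bandHeight >= object@imageSize[1])
    return("bandHeight must leave fiducial margins")
  if (object@cylinderRadius >= object@axisDistance)
    return("camera must be outside the cylinder")
  TRUE
})

#' @param imageSize,nRoots,widthRange,rootIntensity,speckleDensity,fiducialCell
#'   see the class slots.
#' @param bandHeight,cylinderRadius,axisDistance,backgroundDepth,focal,seed
#'   see the class slots.
#' @rdname SceneSpec-class
#' @export
sceneSpec <- function(imageSize = c(240L, 640L), nRoots = 12L,
                      widthRange = c(4, 9), rootIntensity = 0.9,
                      speckleDensity = 0.15, fiducialCell = 8L,
                      bandHeight = 140L, cylinderRadius = 60,
                      axisDistance = 245, backgroundDepth = 400,
                      focal = 1800, seed = 1L) {
  new("SceneSpec", imageSize = as.integer(imageSize),
      nRoots = as.integer(nRoots), widthRange = as.numeric(widthRange),
      rootIntensity = rootIntensity, speckleDensity = speckleDensity,
      fiducialCell = as.integer(fiducialCell),
      bandHeight = as.integer(bandHeight), cylinderRadius = cylinderRadius,
      axisDistance = axisDistance, backgroundDepth = backgroundDepth,
      focal = focal, seed = as.integer(seed))
}

#' GroundTruth: analytic truth of a synthetic scene
#'
#' Truth values use the mean-pixel-scale convention: physical lengths/areas
#' are image-plane quantities scaled by the mean per-pixel surface scale of
#' the cylindrical depth model over the root band (the same convention the
#' calibration equations define for the measurement side).
#'
#' @slot rootMask logical matrix of true root pixels (coverage >= 0.5).
#' @slot skeleton logical matrix of rasterised centrelines.
#' @slot totalLength cm, analytic centreline arc length.
#' @slot totalArea cm^2, analytic projected root area.
#' @slot meanDiameter um, length-weighted mean root width.
#' @slot sPix cm^2 per pixel (mean); \code{lPix} = sqrt(sPix), cm.
#' @slot lPix cm per pixel.
#' @slot dsr true encapsulation, percent of the band covered by roots.
#' @slot viewHomographies list of 3 x 3 matrices mapping each view into the
#'   panorama plane (filled by \code{\link{renderViews}}).
#' @slot intrinsics named fx, fy, cx, cy of the panorama camera.
#' @slot band integer c(rowMin, rowMax) of the root band in the panorama.
#' @slot perRoot data.frame with one row per root: length_px, width_px.
#' @export
setClass("GroundTruth",
  representation(rootMask = "matrix", skeleton = "matrix",
                 totalLength = "numeric", totalArea = "numeric",
                 meanDiameter = "numeric", sPix = "numeric", lPix = "numeric",
                 dsr = "numeric", viewHomographies = "list",
                 intrinsics = "numeric", band = "integer",
                 perRoot = "data.frame"))

setValidity("GroundTruth", function(object) {
  if (object@totalLength > 0) {
    d <- object@totalArea / object@totalLength * .units$um_per_cm
    if (abs(d - object@meanDiameter) > 0.02 * object@meanDiameter)
      return("meanDiameter inconsistent with totalArea / totalLength")
  }
  for (H in object@viewHomographies)
    if (abs(det(H)) < 1e-12) return("view homography not invertible")
  TRUE
})

#' CalibrationResult: physical scale of the image grid
#'
#' Produced by \code{\link{calibrate}} from the depth point cloud of the
#' region of interest: total actual surface area of the ROI, per-pixel area,
#' and per-pixel length.
#'
#' @slot sROI cm^2, actual surface area of the ROI.
#' @slot nPixels ROI pixel count.
#' @slot sPix cm^2 per pixel, \code{sROI / nPixels} exactly.
#' @slot lPix cm per pixel, \code{sqrt(sPix)} exactly.
#' @export
setClass("CalibrationResult",
  representation(sROI = "numeric", nPixels = "numeric", sPix = "numeric",
                 lPix = "numeric"))

setValidity("CalibrationResult", function(object) {
  if (!isTRUE(all.equal(object@sPix, object@sROI / object@nPixels,
                        tolerance = 1e-12)))
    return("sPix must equal sROI / nPixels")
  if (!isTRUE(all.equal(object@lPix, sqrt(object@sPix), tolerance = 1e-12)))
    return("lPix must equal sqrt(sPix)")
  TRUE
})

#' @param sROI ROI surface area, cm^2.
#' @param nPixels ROI pixel count.
#' @rdname CalibrationResult-class
#' @export
calibrationResult <- function(sROI, nPixels) {
  sPix <- sROI / nPixels
  new("CalibrationResult", sROI = sROI, nPixels = nPixels, sPix = sPix,
      lPix = sqrt(sPix))
}

#' PredictionModel: univariate allometric linear model
#'
#' Slope and intercept of a linear prediction y = slope * x + intercept.
#' \code{\link{referenceModel}} returns the coefficients fitted on pumpkin
#' rootstock plug seedlings that ship with the package;
#' \code{\link{fitPredictionModel}} refits from data.
#'
#' @slot slope,intercept model coefficients.
#' @slot nFit number of samples behind the fit (NA for shipped models).
#' @slot r2 coefficient of determination (NA for shipped models).
#' @export
setClass("PredictionModel",
  representation(slope = "numeric", intercept = "numeric", nFit = "numeric",
                 r2 = "numeric"))

setValidity("PredictionModel", function(object) {
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    return("slope and intercept must be finite")
  TRUE
})

#' @param slope,intercept coefficients.
#' @param nFit,r2 optional fit metadata.
#' @rdname PredictionModel-class
#' @export
predictionModel <- function(slope, intercept, nFit = NA_real_, r2 = NA_real_) {
  new("PredictionModel", slope = slope, intercept = intercept,
      nFit = as.numeric(nFit), r2 = as.numeric(r2))
}

#' PhenotypeReport: all measured and predicted phenotypes
#'
#' Units follow the field convention: diameters in micrometres, areas in
#' cm^2, lengths in cm, volume in cm^3, encapsulation in percent.
#'
#' @slot plantId identifier used in tabular output.
#' @slot adtr average diameter of total root, um.
#' @slot sasr surface area of surface root, cm^2.
#' @slot dsr density of surface root (encapsulation), percent.
#' @slot sa surface soil (matrix) area, cm^2.
#' @slot satrp predicted surface area of total root, cm^2.
#' @slot ltr calculated length of total root, cm.
#' @slot ltrp predicted length of total root, cm.
#' @slot vtr volume of total root, cm^3.
#' @export
setClass("PhenotypeReport",
  representation(plantId = "character", adtr = "numeric", sasr = "numeric",
                 dsr = "numeric", sa = "numeric", satrp = "numeric",
                 ltr = "numeric", ltrp = "numeric", vtr = "numeric"))

setValidity("PhenotypeReport", function(object) {
  vals <- c(object@adtr, object@sasr, object@dsr, object@sa, object@satrp,
            object@ltr, object@ltrp, object@vtr)
  if (any(!is.finite(vals))) return("all phenotypes must be finite")
  if (any(vals < 0)) return("all phenotypes must be non-negative")
  if (object@dsr > 100) return("dsr is a percentage in [0, 100]")
  vtr <- pi * (object@adtr / .units$um_per_cm / 2)^2 * object@ltrp
  if (abs(vtr - object@vtr) > 1e-6 * max(1, vtr))
    return("vtr inconsistent with cylinder model from adtr and ltrp")
  TRUE
})
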