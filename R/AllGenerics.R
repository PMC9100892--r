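#' @name accessors
#' @title Accessors for RootBallPheno classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots.
#' @param object an object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("colorData", function(object) standardGeneric("colorData"))
#' @rdname accessors
#' @export
setGeneric("depthData", function(object) standardGeneric("depthData"))
#' @rdname accessors
#' @export
setGeneric("intrinsics", function(object) standardGeneric("intrinsics"))
#' @rdname accessors
#' @export
setGeneric("pixelArea", function(object) standardGeneric("pixelArea"))
#' @rdname accessors
#' @export
setGeneric("pixelLength", function(object) standardGeneric("pixelLength"))
#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(object)
  standardGeneric("modelCoefficients"))
#' @rdname accessors
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setMethod("colorData", "RGBDFrame", function(object) object@color)
#' @rdname accessors
#' @export
setMethod("depthData", "RGBDFrame", function(object) object@depth)
#' @rdname accessors
#' @export
setMethod("intrinsics", "RGBDFrame", function(object) object@intrinsics)
#' @rdname accessors
#' @export
setMethod("intrinsics", "GroundTruth", function(object) object@intrinsics)
#' @rdname accessors
#' @export
setMethod("pixelArea", "CalibrationResult", function(object) object@sPix)
#' @rdname accessors
#' @export
setMethod("pixelLength", "CalibrationResult", function(object) object@lPix)
#' @rdname accessors
#' @export
setMethod("modelCoefficients", "PredictionModel", function(object)
  c(slope = object@slope, intercept = object@intercept))

#' @rdname accessors
#' @export
setMethod("phenotypes", "PhenotypeReport", function(object) {
  data.frame(plant_id = object@plantId, ADTR_um = object@adtr,
             SASR_cm2 = object@sasr, DSR_pct = object@dsr,
             Sa_cm2 = object@sa,
             SATRP_cm2 = object@satrp, LTR_cm = object@ltr,
             LTRP_cm = object@ltrp, VTR_cm3 = object@vtr,
             stringsAsFactors = FALSE)
})

setMethod("show", "RGBDFrame", function(object) {
  d <- dim(object@depth)
  cat("RGBDFrame:", d[1], "x", d[2], "px;",
      sprintf("depth %.0f-%.0f mm;", min(object@depth[object@depth > 0]),
              max(object@depth)),
      sprintf("fx=%.0f fy=%.0f cx=%.1f cy=%.1f\n",
              object@intrinsics["fx"], object@intrinsics["fy"],
              object@intrinsics["cx"], object@intrinsics["cy"]))
})

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec:", object@imageSize[1], "x", object@imageSize[2], "px,",
      object@nRoots, "roots, width", object@widthRange[1], "-",
      object@widthRange[2], "px, seed", object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: length %.2f cm, area %.3f cm2, mean diameter %.0f um, DSR %.1f%%\n",
    object@totalLength, object@totalArea, object@meanDiameter, object@dsr))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: S_ROI %.3f cm2 over %d px; S_pix %.3g cm2, L_pix %.4g cm\n",
    object@sROI, as.integer(object@nPixels), object@sPix, object@lPix))
})

setMethod("show", "PredictionModel", function(object) {
  cat(sprintf("PredictionModel: y = %.5f x + %.5f", object@slope,
              object@intercept))
  if (is.finite(object@r2)) cat(sprintf(" (n = %d, r2 = %.4f)",
                                        as.integer(object@nFit), object@r2))
  cat("\n")
})

setMethod("show", "PhenotypeReport", function(object) {
  cat("PhenotypeReport for", object@plantId, "\n")
  cat(sprintf("  ADTR  %8.1f um   (average diameter of total root)\n",
              object@adtr))
  cat(sprintf("  SASR  %8.3f cm2  (surface area of surface root)\n",
              object@sasr))
  cat(sprintf("  DSR   %8.2f %%    (encapsulation)\n", object@dsr))
  cat(sprintf("  SATRP %8.3f cm2  (predicted surface area of total root)\n",
              object@satrp))
  cat(sprintf("  LTR   %8.2f cm   (calculated length of total root)\n",
              object@ltr))
  cat(sprintf("  LTRP  %8.2f cm   (predicted length of total root)\n",
              object@ltrp))
  cat(sprintf("  VTR   %8.4f cm3  (volume of total root)\n", object@vtr))
})
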