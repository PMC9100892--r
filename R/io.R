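# File formats: 8-bit PNG for colour and masks, 16-bit TIFF (integer
# millimetres) for depth, JSON for intrinsics/homographies/reports, CSV
# for tables.

#' Write / read a colour image or mask as PNG
#'
#' @param img matrix or H x W x 3 array in [0, 1] (logical masks are
#'   written as 0/1).
#' @param path file path.
#' @return \code{readImagePNG} returns a matrix or array in [0, 1].
#' @export
writeImagePNG <- function(img, path) {
  if (is.logical(img)) img <- img * 1
  png::writePNG(clamp01(img), path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Write / read a depth map as 16-bit TIFF in millimetres
#'
#' Depth is rounded to integer millimetres (the native unit of time-of-
#' flight sensors) and stored losslessly in 16 bits.
#'
#' @param depth matrix, mm.
#' @param path file path.
#' @return \code{readDepth} returns the depth matrix in mm.
#' @export
writeDepth <- function(depth, path) {
  stopifnot(max(depth) < 65536)
  tiff::writeTIFF(round(depth) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeDepth
#' @export
readDepth <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

#' Write / read camera intrinsics as JSON
#' @param intr named vector fx, fy, cx, cy.
#' @param path file path.
#' @export
writeIntrinsics <- function(intr, path) {
  jsonlite::write_json(as.list(intr[c("fx", "fy", "cx", "cy")]), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeIntrinsics
#' @export
readIntrinsics <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read an RGBDFrame
#'
#' Writes \code{<prefix>_color.png}, \code{<prefix>_depth.tif} and
#' \code{<prefix>_intrinsics.json}.
#'
#' @param frame an \linkS4class{RGBDFrame}.
#' @param prefix path prefix.
#' @export
writeFrame <- function(frame, prefix) {
  writeImagePNG(colorData(frame), paste0(prefix, "_color.png"))
  writeDepth(depthData(frame), paste0(prefix, "_depth.tif"))
  writeIntrinsics(intrinsics(frame), paste0(prefix, "_intrinsics.json"))
  invisible(prefix)
}

#' @rdname writeFrame
#' @export
readFrame <- function(prefix) {
  RGBDFrame(readImagePNG(paste0(prefix, "_color.png")),
            readDepth(paste0(prefix, "_depth.tif")),
            readIntrinsics(paste0(prefix, "_intrinsics.json")))
}

#' Write synthetic ground truth to disk
#'
#' Masks as PNG, homographies + intrinsics + scalars as JSON, per-root
#' table as CSV.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param dir output directory.
#' @export
writeGroundTruth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeImagePNG(gt@rootMask, file.path(dir, "gt_root_mask.png"))
  writeImagePNG(gt@skeleton, file.path(dir, "gt_skeleton.png"))
  jsonlite::write_json(
    list(total_length_cm = gt@totalLength, total_area_cm2 = gt@totalArea,
         mean_diameter_um = gt@meanDiameter, s_pix_cm2 = gt@sPix,
         l_pix_cm = gt@lPix, dsr_pct = gt@dsr,
         intrinsics = as.list(gt@intrinsics), band = gt@band,
         view_homographies = lapply(gt@viewHomographies, unname)),
    file.path(dir, "gt_scene.json"), auto_unbox = TRUE, digits = NA)
  write.csv(gt@perRoot, file.path(dir, "gt_roots.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write / read a phenotype report
#'
#' JSON keeps full precision; the CSV is a single row with 15 significant
#' digits, so both round-trip losslessly at 12 significant digits.
#'
#' @param report a \linkS4class{PhenotypeReport}.
#' @param jsonPath,csvPath output paths (NULL skips that format).
#' @export
writeReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  df <- phenotypes(report)
  if (!is.null(jsonPath))
    jsonlite::write_json(as.list(df), jsonPath, auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(csvPath)) {
    fmt <- df
    for (k in seq_along(fmt)) if (is.numeric(fmt[[k]]))
      fmt[[k]] <- sprintf("%.15g", fmt[[k]])
    write.csv(fmt, csvPath, row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}

#' @rdname writeReport
#' @param path JSON or CSV path produced by \code{writeReport}.
#' @export
readReport <- function(path) {
  df <- if (grepl("\\.json$", path))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else read.csv(path)
  assembleReport(df$plant_id, df$ADTR_um, df$SASR_cm2, df$DSR_pct,
                 df$Sa_cm2, df$SATRP_cm2, df$LTR_cm, df$LTRP_cm,
                 df$VTR_cm3)
}
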