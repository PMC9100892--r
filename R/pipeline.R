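# Pipeline orchestration: simulate -> stitch -> preprocess -> segment ->
# measure, with a serializable configuration, per-stage logging, batch
# support, and validation against synthetic ground truth.

#' Default pipeline configuration
#'
#' A nested list with one section per stage plus a global seed and model
#' source. Unknown keys are rejected by \code{\link{pipelineConfig}}.
#'
#' @return named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    model_source = "reference",
    synth = list(image_size = c(240L, 640L), n_roots = 12L,
                 width_range = c(4, 9), n_views = 4L, overlap_frac = 0.4,
                 noise_sd = 2 / 255),
    stitch = list(reference_index = 1L, anms_n = 400L, reproj_tol = 2,
                  roi_inset = 6L),
    preprocess = list(gain = 1.4, gamma = 0.8, dilate_r = 10L, erode_r = 3L,
                      open_r = 3L, gamma_h = 1.5, gamma_l = 0.5),
    segment = list(sigma_min = 1, sigma_max = 6, n_scales = 6L, beta = 0.5,
                   c = "auto", min_area = 30L, hysteresis_low = 0.5,
                   refine = "intensity"),
    phenotype = list(erosion_r = 7L, median_k = 3L, smooth_sigma = 0)
  )
}

#' Build and validate a pipeline configuration
#'
#' Merges overrides into \code{\link{defaultPipelineConfig}}; unknown
#' sections or keys are an error, so typos cannot silently fall back to
#' defaults.
#'
#' @param ... named overrides, either whole sections (as lists) or
#'   \code{seed} / \code{model_source}.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- defaultPipelineConfig()
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(cfg[[nm]])) {
      for (k in names(over[[nm]])) {
        if (!k %in% names(cfg[[nm]]))
          stop("unknown config key: ", nm, "$", k)
        cfg[[nm]][[k]] <- over[[nm]][[k]]
      }
    } else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) pipelineConfig(yaml::read_yaml(path))

# Short stable hash of the configuration (polynomial rolling hash over
# its JSON form), embedded in outputs so artifacts are traceable to
# their parameters.
configHash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("stageFailure", "error", "condition"),
      list(message = sprintf("stage '%s' failed: %s", stage,
                             conditionMessage(e)),
           call = NULL, stage = stage)))
  })
}

#' Run the full phenotyping pipeline
#'
#' Executes simulate (or load) -> stitch -> preprocess -> segment ->
#' measure and returns the phenotype report plus intermediates. With
#' \code{input = "simulate"} a synthetic scene is generated (ground truth
#' returned alongside); otherwise \code{input} is a directory holding
#' frames written by \code{\link{writeFrame}} with prefixes
#' \code{view_1 .. view_n}.
#'
#' @param config configuration from \code{\link{pipelineConfig}}.
#' @param input \code{"simulate"} or a directory of frames.
#' @param outDir optional directory for artifacts (images, report).
#' @param plantId identifier used in the report.
#' @param stitchViews if FALSE in simulate mode, the generator panorama is
#'   measured directly (no view rendering/stitching) - useful for isolating
#'   measurement behaviour from registration.
#' @return list with \code{report}, \code{gt} (or NULL), \code{stitched},
#'   \code{rootMask}, \code{foreground}, \code{nonOverlap}, \code{skeleton},
#'   \code{calibration}, \code{configHash}.
#' @export
runPipeline <- function(config = pipelineConfig(), input = "simulate",
                        outDir = NULL, plantId = "plant-1",
                        stitchViews = TRUE) {
  hash <- configHash(config)
  gt <- NULL
  simulate <- identical(input, "simulate")
  if (simulate) {
    sy <- config$synth
    spec <- sceneSpec(imageSize = sy$image_size, nRoots = sy$n_roots,
                      widthRange = sy$width_range, seed = config$seed)
    scene <- runStage("simulate", generateRootScene(spec))
    gt <- scene$gt
    stageLog("simulate", "scene seed ", config$seed, ", config ", hash)
    if (stitchViews) {
      rv <- runStage("simulate",
                     renderViews(scene, nViews = sy$n_views,
                                 overlapFrac = sy$overlap_frac,
                                 noiseSd = sy$noise_sd,
                                 seed = config$seed + 1L))
      frames <- rv$frames; gt <- rv$gt
    }
  } else {
    frames <- runStage("load", {
      prefixes <- file.path(input,
        sub("_color\\.png$", "",
            basename(sort(list.files(input, "^view_[0-9]+_color\\.png$",
                                     full.names = TRUE)))))
      if (!length(prefixes)) stop("no view_*_color.png frames in ", input)
      lapply(prefixes, readFrame)
    })
  }
  st <- config$stitch
  if (simulate && !stitchViews) {
    stitched <- RGBDFrame(scene$color, scene$depth, scene$intrinsics)
  } else {
    stitched <- runStage("stitch", {
      Hs <- registerViews(frames, referenceIndex = st$reference_index,
                          anmsN = st$anms_n, reprojTol = st$reproj_tol,
                          seed = config$seed + 2L)
      compositeViews(frames, Hs, st$reference_index)$frame
    })
    stageLog("stitch", length(frames), " views composited")
  }
  pp <- config$preprocess
  pre <- runStage("preprocess", {
    enh <- enhance(colorData(stitched), pp$gain, pp$gamma)
    bg <- removeBackground(enh, dilateR = pp$dilate_r, erodeR = pp$erode_r,
                           openR = pp$open_r)
    list(enh = enh, mask = bg$mask)
  })
  stageLog("preprocess", "foreground ", sum(pre$mask), " px")
  roiFrame <- runStage("roi", {
    idx <- which(pre$mask, arr.ind = TRUE)
    ins <- st$roi_inset
    y0 <- min(idx[, 1]) + ins; y1 <- max(idx[, 1]) - ins
    x0 <- min(idx[, 2]) + ins; x1 <- max(idx[, 2]) - ins
    if (y1 <= y0 || x1 <= x0) stop("foreground too small for the ROI inset")
    extractROI(stitched, c(x0, y0, x1 - x0 + 1L, y1 - y0 + 1L))
  })
  idx <- which(pre$mask, arr.ind = TRUE)
  ins <- st$roi_inset
  rows <- (min(idx[, 1]) + ins):(max(idx[, 1]) - ins)
  cols <- (min(idx[, 2]) + ins):(max(idx[, 2]) - ins)
  fgROI <- pre$mask[rows, cols]
  seg <- runStage("segment", {
    enhROI <- enhance(colorData(stitched), pp$gain, pp$gamma)[rows, cols, ,
                                                              drop = FALSE]
    hom <- homomorphicFilter(toGray(enhROI) * fgROI, pp$gamma_h, pp$gamma_l)
    sg <- config$segment
    vp <- vesselnessParams(sg$sigma_min, sg$sigma_max, sg$n_scales,
                           sg$beta, sg$c)
    vmap <- multiscaleVesselness(hom, vp)
    mask <- binarizeMask(vmap, fgROI, minArea = sg$min_area,
                         hysteresisLow = sg$hysteresis_low)
    if (identical(sg$refine, "intensity"))
      mask <- refineRootMask(mask, hom, minArea = sg$min_area) & fgROI
    list(vmap = vmap, mask = mask)
  })
  stageLog("segment", sum(seg$mask), " root px")
  ph <- config$phenotype
  res <- runStage("measure", {
    if (all(depthData(roiFrame) == 0)) stop("missing or empty depth data")
    # depth loaded from disk is quantized to integer millimetres, whose
    # steps corrupt finite-difference patch areas; smooth unless the
    # configuration already asks for it
    smoothSigma <- if (!simulate && ph$smooth_sigma == 0) 2
                   else ph$smooth_sigma
    cal <- calibrate(depthData(roiFrame), intrinsics(roiFrame), fgROI,
                     smoothSigma = smoothSigma)
    no <- extractNonoverlapping(seg$mask, ph$erosion_r, ph$median_k)
    sk <- skeletonLength(no, cal, smooth = TRUE)
    di <- averageDiameter(no, sk$lengthCm, cal)
    enc <- encapsulation(seg$mask, fgROI)
    sa <- pixelArea(cal) * enc$pixAll
    sasr <- enc$dsr / 100 * sa
    mSATR <- if (identical(config$model_source, "reference"))
      referenceModel("satr") else readModel(config$model_source, "satr")
    mLTR <- if (identical(config$model_source, "reference"))
      referenceModel("ltr") else readModel(config$model_source, "ltr")
    satrp <- predictTotalSurfaceArea(sasr, mSATR)
    lt <- predictTotalLength(satrp, di$adtrUm, mLTR)
    vtr <- totalVolume(di$adtrUm, lt[["ltrp"]])
    list(cal = cal, no = no, sk = sk,
         report = assembleReport(plantId, di$adtrUm, sasr, enc$dsr, sa,
                                 satrp, lt[["ltr"]], lt[["ltrp"]], vtr))
  })
  stageLog("measure", "ADTR ", round(res$report@adtr), " um")
  out <- list(report = res$report, gt = gt, stitched = stitched,
              rootMask = seg$mask, foreground = fgROI,
              nonOverlap = res$no, skeleton = res$sk$skeleton,
              calibration = res$cal, configHash = hash)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeImagePNG(colorData(stitched), file.path(outDir, "stitched.png"))
    writeImagePNG(fgROI, file.path(outDir, "foreground.png"))
    writeImagePNG(seg$mask, file.path(outDir, "root_mask.png"))
    writeImagePNG(res$no, file.path(outDir, "non_overlap.png"))
    writeImagePNG(res$sk$skeleton, file.path(outDir, "skeleton.png"))
    tiff::writeTIFF(seg$vmap$v, file.path(outDir, "vesselness.tif"),
                    bits.per.sample = 16L)
    writeReport(res$report, file.path(outDir, "report.json"),
                file.path(outDir, "report.csv"))
    jsonlite::write_json(list(config_hash = hash, config = config),
                         file.path(outDir, "run.json"), auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(gt)) writeGroundTruth(gt, outDir)
  }
  out
}

# Load slope/intercept models from a JSON file with fields satr/ltr.
readModel <- function(path, which) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  predictionModel(j[[which]]$slope, j[[which]]$intercept)
}

#' Compare a report against synthetic ground truth
#'
#' Tabulates absolute and relative errors for the phenotypes the
#' generator knows the truth of (diameter, surface-root area,
#' encapsulation). Total-root predictions have no synthetic truth (the
#' generator only creates surface roots) and are not rows here.
#'
#' @param report a \linkS4class{PhenotypeReport}.
#' @param gt a \linkS4class{GroundTruth}.
#' @return data.frame with phenotype, measured, truth, abs_error,
#'   rel_error.
#' @export
validateAgainstTruth <- function(report, gt) {
  tab <- data.frame(
    phenotype = c("ADTR_um", "SASR_cm2", "DSR_pct"),
    measured = c(report@adtr, report@sasr, report@dsr),
    truth = c(gt@meanDiameter, gt@totalArea, gt@dsr))
  tab$abs_error <- abs(tab$measured - tab$truth)
  tab$rel_error <- tab$abs_error / tab$truth
  tab
}

#' Run a batch of simulated plants
#'
#' Runs the pipeline over \code{n} seeds and aggregates per-plant reports
#' and (optionally) truth-validation error tables, including the median
#' relative error per phenotype.
#'
#' @param n number of plants.
#' @param config base configuration; seeds are \code{config$seed + 0:(n-1)}.
#' @param outDir optional artifact directory; a summary CSV is written.
#' @param stitchViews passed to \code{\link{runPipeline}}.
#' @return list with \code{reports} (data.frame, one row per plant),
#'   \code{errors} (long data.frame) and \code{medianRelError} (named
#'   vector).
#' @export
runBatch <- function(n, config = pipelineConfig(), outDir = NULL,
                     stitchViews = TRUE) {
  reports <- vector("list", n); errors <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config; cfg$seed <- config$seed + i - 1L
    res <- runPipeline(cfg, plantId = sprintf("plant-%d", i),
                       stitchViews = stitchViews)
    reports[[i]] <- phenotypes(res$report)
    if (!is.null(res$gt)) {
      e <- validateAgainstTruth(res$report, res$gt)
      e$plant_id <- sprintf("plant-%d", i)
      errors[[i]] <- e
    }
  }
  reports <- do.call(rbind, reports)
  errors <- if (length(errors) && !is.null(errors[[1L]]))
    do.call(rbind, errors) else NULL
  med <- if (!is.null(errors))
    tapply(errors$rel_error, errors$phenotype, median) else NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(reports, file.path(outDir, "batch_reports.csv"),
              row.names = FALSE)
    if (!is.null(errors))
      write.csv(errors, file.path(outDir, "batch_errors.csv"),
                row.names = FALSE)
  }
  list(reports = reports, errors = errors, medianRelError = med)
}
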