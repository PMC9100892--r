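planeDepth <- function(h, w, z) matrix(z, h, w)
testIntr <- c(fx = 500, fy = 500, cx = 50.5, cy = 50.5)

test_that("calibration matches pinhole closed forms and conserves area", {
  # fronto-parallel plane at 500 mm with f = 500 px: 1 mm^2 = 0.01 cm^2/px
  cal <- calibrate(planeDepth(100, 100, 500), testIntr)
  expect_equal(pixelArea(cal), 0.01, tolerance = 1e-3)
  # conservation is exact by construction
  expect_equal(pixelArea(cal) * cal@nPixels, cal@sROI, tolerance = 1e-14)
  expect_equal(pixelLength(cal), sqrt(pixelArea(cal)), tolerance = 1e-14)

  # Eq-style arithmetic: S_ROI = 100 cm^2 over 10,000 px
  c2 <- calibrationResult(100, 10000)
  expect_identical(pixelArea(c2), 0.01)
  expect_identical(pixelLength(c2), 0.1)

  # plane tilted 60 degrees: area grows by 1/cos(60) = 2
  h <- 101; w <- 101
  z0 <- 500
  # depth so the surface tilts about the vertical axis by 60 degrees:
  # dz/dx_world = tan(60); with x = (u - cx) z / f, solve z(u)
  u <- seq_len(w) - testIntr["cx"]
  zcol <- z0 / (1 - u * tan(pi / 3) / testIntr["fx"])
  tilted <- matrix(rep(zcol, each = h), h, w)
  keep <- matrix(FALSE, h, w); keep[, 40:62] <- TRUE  # stay near centre
  calT <- calibrate(tilted, testIntr, keep)
  flat <- calibrate(planeDepth(h, w, z0), testIntr, keep)
  expect_equal(calT@sROI / flat@sROI, 2, tolerance = 0.01)

  # invalid-depth handling
  expect_error(calibrate(matrix(0, 5, 5), testIntr), "no valid depth")
  holey <- planeDepth(50, 50, 500); holey[20:22, 20:22] <- 0
  calH <- calibrate(holey, testIntr)
  expect_equal(pixelArea(calH), 0.01, tolerance = 2e-3)
})

test_that("non-overlap extraction keeps thin roots and drops wide cores", {
  # a 3-px line vanishes under erosion r = 2, so it is wholly non-overlapping
  thin <- matrix(FALSE, 60, 120); thin[30:32, 10:110] <- TRUE
  no <- extractNonoverlapping(thin, 2L, 3L)
  expect_identical(no, thin)

  # 20-px band: expected output derived from a brute-force morphological
  # oracle (erode, 3x3 median, dilate, subtract)
  wide <- matrix(FALSE, 80, 140); wide[30:49, 11:130] <- TRUE
  no2 <- extractNonoverlapping(wide, 2L, 3L)
  se <- RootBallPheno:::brushDisc(2L) > 0
  er <- morphOracle(wide, se, "erode")
  med <- medianOracle(er)
  restored <- morphOracle(med, se, "dilate")
  expect_identical(no2, wide & !restored)
  # the restored interior excludes most of the band from the output
  expect_lt(sum(no2) / sum(wide), 0.2)

  expect_identical(extractNonoverlapping(matrix(FALSE, 10, 10)),
                   matrix(FALSE, 10, 10))
})

test_that("skeleton length applies the 1.2 pixel-mix factor", {
  cal <- calibrationResult(100, 10000)  # L_pix = 0.1 cm
  line <- matrix(FALSE, 20, 120); line[10, 11:110] <- TRUE  # 100 px
  sk <- skeletonLength(line, cal)
  expect_identical(sk$nPixels, 100L)
  expect_equal(sk$lengthCm, 100 * 1.2 * 0.1, tolerance = 1e-12)

  expect_equal(skeletonLength(matrix(FALSE, 5, 5), cal)$lengthCm, 0)

  # 45-degree chain: the printed factor under-reports the Euclidean oracle
  n <- 80L
  diag45 <- matrix(FALSE, 100, 100)
  diag45[cbind(10 + seq_len(n), 10 + seq_len(n))] <- TRUE
  skd <- skeletonLength(diag45, cal)
  euclid <- chainLengthOracle(diag45, pixelLength(cal))
  expect_equal(skd$euclideanCm, euclid, tolerance = 1e-9)
  expect_equal(skd$lengthCm / euclid, 1.2 / sqrt(2), tolerance = 0.02)
})

test_that("average diameter follows the area/length ratio", {
  cal <- calibrationResult(100, 10000)
  # SASR_NO = 0.6 cm^2 over 12 cm -> 0.05 cm = 500 um
  mask60 <- matrix(FALSE, 10, 10); mask60[seq_len(60)] <- TRUE
  di <- averageDiameter(mask60, 12, cal)
  expect_equal(di$sasrNoCm2, 0.6, tolerance = 1e-12)
  expect_equal(di$adtrUm, 500, tolerance = 1e-9)

  expect_error(averageDiameter(mask60, 0, cal), class = "undefinedDiameter")

  # straight oblique roots of commanded width 500 um (5 px at 100 um/px):
  # recovered within 15% despite thinning and the 1.2 factor
  h <- 260L; w <- 260L
  mask <- matrix(FALSE, h, w)
  for (ang in c(15, 35, 55, 75) * pi / 180) {
    t <- seq(0, 200)
    pts <- cbind(30 + t * cos(ang), 25 + t * sin(ang))
    mask <- mask | RootBallPheno:::.rasterTube(pts, 5, h, w) >= 0.5
  }
  calPix <- calibrationResult(0.01^2 * h * w, h * w)  # 0.01 cm = 100 um/px
  no <- extractNonoverlapping(mask, 5L, 3L)
  sk <- skeletonLength(no, calPix, smooth = TRUE)
  d2 <- averageDiameter(no, sk$lengthCm, calPix)
  expect_lt(abs(d2$adtrUm - 500) / 500, 0.15)
})

test_that("encapsulation is a pixel ratio with monotone response", {
  fg <- matrix(FALSE, 100, 100); fg[seq_len(10000) <= 10000] <- TRUE
  root <- matrix(FALSE, 100, 100); root[seq_len(2000)] <- TRUE
  enc <- encapsulation(root, fg)
  expect_equal(enc$dsr, 20)
  expect_equal(encapsulation(matrix(FALSE, 10, 10),
                             matrix(TRUE, 10, 10))$dsr, 0)
  expect_equal(encapsulation(fg, fg)$dsr, 100)
  expect_error(encapsulation(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)),
               "empty matrix")

  # adding root pixels to a fixed foreground strictly increases DSR
  r2 <- root; r2[3000:3100] <- TRUE
  expect_gt(encapsulation(r2, fg)$dsr, enc$dsr)
})

test_that("allometric predictions reproduce the shipped coefficients", {
  expect_equal(predictTotalSurfaceArea(0), 7.6522, tolerance = 1e-12)
  expect_equal(predictTotalSurfaceArea(10), 2.16556 * 10 + 7.6522,
               tolerance = 1e-12)
  expect_equal(predictTotalSurfaceArea(5, predictionModel(1, 0)), 5)

  lt0 <- predictTotalLength(0, 500)
  expect_equal(unname(lt0["ltr"]), 0)
  expect_equal(unname(lt0["ltrp"]), 16.83062, tolerance = 1e-12)
  lt10 <- predictTotalLength(5, 5000)  # 5 cm^2 / 0.5 cm -> LTR = 10 cm
  expect_equal(unname(lt10["ltr"]), 10, tolerance = 1e-12)
  expect_equal(unname(lt10["ltrp"]), 2.9723 * 10 + 16.83062,
               tolerance = 1e-12)
  expect_equal(unname(predictTotalLength(5, 500)["ltr"]), 100)
  expect_error(predictTotalLength(5, 0), "adtrUm")

  expect_equal(totalVolume(0, 10), 0)
  expect_equal(totalVolume(500, 46.55362), pi * 0.025^2 * 46.55362,
               tolerance = 1e-12)
  # square law in the diameter
  expect_equal(totalVolume(1000, 10) / totalVolume(500, 10), 4)
})

test_that("model fitting is exact on lines and recovers generator truth", {
  x <- c(1, 2, 3, 4.5, 7)
  m <- fitPredictionModel(x, 2 * x + 1)
  expect_equal(unname(modelCoefficients(m)), c(2, 1), tolerance = 1e-12)
  expect_equal(m@r2, 1, tolerance = 1e-12)

  expect_error(fitPredictionModel(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(fitPredictionModel(rep(2, 5), 1:5), "constant")

  d <- generateRegressionDataset(200, 2.16556, 7.6522, 1, seed = 31L)
  fit <- fitPredictionModel(d$x, d$y)
  sm <- summary(lm(y ~ x, d))$coefficients
  expect_lt(abs(fit@slope - 2.16556), 3 * sm["x", "Std. Error"])
  expect_lt(abs(fit@intercept - 7.6522), 3 * sm["(Intercept)", "Std. Error"])
})

test_that("phenotype reports validate, round-trip, and catch tampering", {
  lt <- predictTotalLength(predictTotalSurfaceArea(1.5), 650)
  rep <- assembleReport("p1", 650, 1.5, 22.1, 6.79,
                        predictTotalSurfaceArea(1.5), lt[["ltr"]],
                        lt[["ltrp"]], totalVolume(650, lt[["ltrp"]]))
  df <- phenotypes(rep)
  expect_true(all(is.finite(unlist(df[-1]))))

  td <- withr::local_tempdir()
  writeReport(rep, file.path(td, "r.json"), file.path(td, "r.csv"))
  rj <- readReport(file.path(td, "r.json"))
  rc <- readReport(file.path(td, "r.csv"))
  for (sl in c("adtr", "sasr", "dsr", "satrp", "ltr", "ltrp", "vtr")) {
    expect_equal(slot(rj, sl), slot(rep, sl), tolerance = 1e-12)
    expect_equal(slot(rc, sl), slot(rep, sl), tolerance = 1e-12)
  }

  expect_error(assembleReport("p", NA, 1, 1, 1, 1, 1, 1, 1), "missing")
  # tampered volume violates the cylinder-consistency invariant
  expect_error(assembleReport("p1", 650, 1.5, 22.1, 6.79,
                              predictTotalSurfaceArea(1.5), lt[["ltr"]],
                              lt[["ltrp"]], 99), "inconsistent")
})

test_that("measured diameter is stable across rendering resolution", {
  # the same physical root layout rasterized at 1x (100 um/px) and 2x
  # (50 um/px): ADTR in physical units should agree within 5%
  measureAt <- function(scale) {
    h <- 300L * scale; w <- 300L * scale
    mask <- matrix(FALSE, h, w)
    angles <- c(15, 35, 55, 75) * pi / 180
    origins <- list(c(20, 20), c(160, 20), c(20, 160), c(160, 160))
    for (i in seq_along(angles)) {  # disjoint tubes, one per quadrant
      t <- seq(0, 100 * scale)
      pts <- cbind(origins[[i]][1] * scale + t * cos(angles[i]),
                   origins[[i]][2] * scale + t * sin(angles[i]))
      mask <- mask | RootBallPheno:::.rasterTube(pts, 5 * scale, h, w) >= 0.5
    }
    pxCm <- 0.01 / scale
    cal <- calibrationResult(pxCm^2 * h * w, h * w)
    no <- extractNonoverlapping(mask, 5L * scale, 3L)
    sk <- skeletonLength(no, cal, smooth = TRUE)
    averageDiameter(no, sk$lengthCm, cal)$adtrUm
  }
  a1 <- measureAt(1L); a2 <- measureAt(2L)
  expect_lt(abs(a1 - a2) / a1, 0.05)
})
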