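test_that("corner detection handles flat images and covers the fiducial", {
  expect_equal(nrow(detectCorners(matrix(0.5, 64, 64))), 0L)

  spec <- sceneSpec(imageSize = c(240L, 240L), seed = 5L)
  fid <- generateFiducialBackground(spec)
  cs <- detectCorners(fid, maxCorners = 3000L, anmsN = 1000L)
  # spatial coverage: >= 80% of a coarse cell grid contains a corner
  gridN <- 8L
  gx <- ceiling(cs$x / (240 / gridN)); gy <- ceiling(cs$y / (240 / gridN))
  expect_gte(length(unique(paste(gx, gy))) / gridN^2, 0.8)
})

test_that("ANMS returns the requested spatially balanced subset", {
  set.seed(7)
  n <- 500L
  x <- runif(n, 1, 300); y <- runif(n, 1, 300); resp <- sort(runif(n),
                                                            decreasing = TRUE)
  sel <- RootBallPheno:::.anmsSelect(x, y, resp, 50L)
  expect_equal(nrow(sel), 50L)
  orc <- anmsOracle(x, y, resp, 50L)
  expect_setequal(round(sel$x, 9), round(x[orc$idx], 9))
  expect_equal(sort(sel$radius, decreasing = TRUE), orc$radius,
               tolerance = 1e-9)
  # the selected subset is at least as spread out as any greedy choice:
  # its smallest suppression radius equals the oracle's
  expect_equal(min(sel$radius), min(orc$radius), tolerance = 1e-9)
})

test_that("descriptor matching finds identity and translation, rejects noise", {
  spec <- sceneSpec(imageSize = c(200L, 200L), seed = 8L)
  img <- generateFiducialBackground(spec)
  cs <- detectCorners(img, anmsN = 200L)
  m <- matchDescriptors(img, cs, img, cs)
  d <- sqrt((m$xA - m$xB)^2 + (m$yA - m$yB)^2)
  expect_gte(mean(d < 1e-9), 0.95)

  # frame B = frame A shifted by a known translation
  big <- generateFiducialBackground(sceneSpec(imageSize = c(240L, 240L),
                                              seed = 9L))
  A <- big[1:200, 1:200]; B <- big[21:220, 31:230]  # B(x) = A(x + 30, y + 20)
  cA <- detectCorners(A, anmsN = 200L); cB <- detectCorners(B, anmsN = 200L)
  mm <- matchDescriptors(A, cA, B, cB)
  dx <- mm$xB - mm$xA; dy <- mm$yB - mm$yA
  good <- abs(dx + 30) <= 1 & abs(dy + 20) <= 1
  expect_gte(mean(good), 0.9)

  # unrelated noise frames: insufficient overlap signalled
  set.seed(1)
  n1 <- matrix(runif(200 * 200), 200); n2 <- matrix(runif(200 * 200), 200)
  c1 <- detectCorners(n1, anmsN = 50L); c2 <- detectCorners(n2, anmsN = 50L)
  expect_error(matchDescriptors(n1, c1, n2, c2),
               class = "insufficientOverlap")
})

test_that("homography estimation is exact on clean data, robust to outliers", {
  H <- matrix(c(1.02, 0.01, 5, -0.015, 0.98, -3, 1e-5, -2e-5, 1), 3, 3,
              byrow = TRUE)
  clean <- simulateMatches(H, n = 40L, seed = 2L)
  est <- estimateHomography(clean, seed = 3L)
  p <- applyHomography(est$H, as.matrix(clean[, c("xA", "yA")]))
  expect_lt(max(sqrt(rowSums((p - as.matrix(clean[, c("xB", "yB")]))^2))),
            1e-6)

  # 80 exact + 20 uniform outliers at tolerance 2 px
  mix <- simulateMatches(H, n = 80L, nOut = 20L, seed = 5L)
  est2 <- estimateHomography(mix, reprojTol = 2, seed = 7L)
  expect_gte(sum(est2$inliers), 78L)
  pc <- applyHomography(est2$H, as.matrix(mix[1:80, c("xA", "yA")]))
  expect_lt(max(sqrt(rowSums((pc - as.matrix(mix[1:80, c("xB", "yB")]))^2))),
            0.5)

  # determinism: same seed, same inlier set
  est3 <- estimateHomography(mix, reprojTol = 2, seed = 7L)
  expect_identical(est2$inliers, est3$inliers)

  expect_error(estimateHomography(clean[1:3, ]), class = "homographyFailure")
})

test_that("homography algebra round-trips", {
  H <- matrix(c(0.97, 0.03, 12, -0.02, 1.04, 7, 2e-5, -1e-5, 1), 3, 3,
              byrow = TRUE)
  xy <- cbind(runif(50, 1, 300), runif(50, 1, 300))
  back <- applyHomography(solve(H), applyHomography(H, xy))
  expect_lt(max(abs(back - xy)), 1e-6)
  expect_equal(normalizeHomography(3.7 * H), H, tolerance = 1e-12)
})

test_that("compositing reproduces the panorama and respects footprints", {
  # single frame under identity: output equals input
  sc <- smallScene(seed = 4L)
  fr <- RGBDFrame(sc$color, sc$depth, sc$intrinsics)
  out <- compositeViews(list(fr), list(diag(3)))
  expect_equal(out$frame@color, fr@color, tolerance = 1e-9)
  expect_equal(out$frame@depth, fr@depth, tolerance = 1e-9)

  # synthetic 4-view set with known homographies: the composite equals the
  # source panorama over the region both cover (canvas (1,1) sits at
  # panorama coordinate (1 + offset))
  rv <- renderViews(sc, overlapFrac = 0.4, noiseSd = 0, seed = 2L)
  cmp <- compositeViews(rv$frames, rv$gt@viewHomographies)
  g <- toGray(colorData(cmp$frame))
  ref <- toGray(sc$color)
  ci <- seq_len(nrow(g)) + cmp$offset[2]; cj <- seq_len(ncol(g)) + cmp$offset[1]
  keepI <- ci >= 1 & ci <= nrow(ref); keepJ <- cj >= 1 & cj <= ncol(ref)
  sub <- g[keepI, keepJ]; refSub <- ref[ci[keepI], cj[keepJ]]
  valid <- depthData(cmp$frame)[keepI, keepJ] > 0
  # bilinear resampling blurs the sharp fiducial block edges; the signal
  # content (low-pass) must agree to ~3 intensity levels, the raw
  # difference is bounded by the edge-interpolation error
  bl <- RootBallPheno:::blurGray
  lowpass <- bl(sub, 2) - bl(refSub, 2)
  expect_lt(sqrt(mean(lowpass[valid]^2)), 3 / 255)
  expect_lt(sqrt(mean((sub - refSub)[valid]^2)), 8 / 255)

  # two adjacent non-overlapping frames: canvas area = sum of footprints
  A <- RGBDFrame(sc$color[, 1:100, ], sc$depth[, 1:100], sc$intrinsics)
  H2 <- diag(3); H2[1, 3] <- 100
  out2 <- compositeViews(list(A, A), list(diag(3), H2))
  expect_equal(prod(dim(depthData(out2$frame))), 2 * nrow(sc$depth) * 100)

  expect_error(compositeViews(list(A), list(matrix(0, 3, 3))),
               "non-invertible")
})

test_that("ROI extraction crops and shifts the principal point", {
  sc <- smallScene(seed = 6L)
  fr <- RGBDFrame(sc$color, sc$depth, sc$intrinsics)
  full <- extractROI(fr, c(1, 1, ncol(sc$depth), nrow(sc$depth)))
  expect_equal(full@color, fr@color)
  expect_equal(full@intrinsics, fr@intrinsics)

  crop <- extractROI(fr, c(11, 11, 100, 100))
  expect_equal(dim(depthData(crop)), c(100L, 100L))
  expect_equal(unname(intrinsics(crop)["cx"]),
               unname(intrinsics(fr)["cx"] - 10))
  expect_equal(unname(intrinsics(crop)["cy"]),
               unname(intrinsics(fr)["cy"] - 10))

  expect_error(extractROI(fr, c(10, 10, 0, 5)), "empty")
  expect_error(extractROI(fr, c(630, 1, 100, 100)), "outside")

  # depth alignment hook is the identity
  expect_identical(alignDepth(fr), fr)
})
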