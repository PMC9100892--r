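test_that("Hessian eigenvalues match a finite-difference oracle and rotate", {
  # constant image: all zero (down to FFT rounding)
  he <- hessianEigen(matrix(0.7, 40, 40), 2)
  expect_lt(max(abs(he$lambda1)), 1e-9)
  expect_lt(max(abs(he$lambda2)), 1e-9)

  # wide vertical bright ridge: lambda2 < 0 at the centre, |lambda1| ~ 0
  n <- 81L; a <- 4; sigma <- 6
  ridge <- matrix(rep(exp(-((seq_len(n) - 41)^2) / (2 * a^2)), each = n), n)
  he <- hessianEigen(ridge, sigma)
  expect_lt(he$lambda2[41, 41], 0)
  expect_lt(abs(he$lambda1[41, 41]), 0.02 * abs(he$lambda2[41, 41]))

  # independent oracle: dnorm-kernel smoothing by direct convolution, then
  # fourth-order finite-difference second derivative, sigma^2-normalized
  k <- dnorm(seq(-30, 30), sd = sigma); k <- k / sum(k)
  smoothRows <- function(m) t(apply(m, 1, function(r)
    stats::convolve(r, rev(k), type = "open")[31:(30 + n)]))
  sm <- smoothRows(t(smoothRows(t(ridge))))
  ctr <- 41
  row5 <- sm[ctr, (ctr - 2):(ctr + 2)]
  ixxFD <- sigma^2 * sum(c(-1, 16, -30, 16, -1) / 12 * row5)
  expect_equal(unname(he$lambda2[ctr, ctr]), ixxFD, tolerance = 1e-3)

  # ordering invariant on a random image
  set.seed(5)
  img <- matrix(runif(48 * 48), 48, 48)
  hr <- hessianEigen(img, 1.5)
  expect_true(all(abs(hr$lambda1) <= abs(hr$lambda2) + 1e-12))

  # eigenvalue maps commute with a lossless 90-degree rotation
  rot90 <- function(m) t(m)[, nrow(m):1]
  h1 <- hessianEigen(img, 2)
  h2 <- hessianEigen(rot90(img), 2)
  inner <- 8:40  # ignore boundary padding effects
  expect_lt(max(abs(rot90(h1$lambda2)[inner, inner] -
                    h2$lambda2[inner, inner])),
            0.01 * max(abs(h1$lambda2)))

  expect_error(hessianEigen(img, 0.2), "sigma")
})

test_that("single-scale vesselness follows the response formula exactly", {
  # lambda2 > 0 is suppressed
  f <- list(lambda1 = matrix(0.1, 2, 2), lambda2 = matrix(0.5, 2, 2))
  expect_equal(vesselnessSingleScale(f, c = 1), matrix(0, 2, 2))

  # ideal tube: |lambda1| ~ 0, lambda2 << 0, S >> c: response -> 1
  f2 <- list(lambda1 = matrix(0, 2, 2), lambda2 = matrix(-100, 2, 2))
  expect_equal(vesselnessSingleScale(f2, beta = 0.5, c = 1),
               matrix(1, 2, 2), tolerance = 1e-6)

  # hand-evaluated point: l1 = l2 = -1, beta = 0.5, c = 1
  f3 <- list(lambda1 = matrix(-1, 1, 1), lambda2 = matrix(-1, 1, 1))
  expect_equal(vesselnessSingleScale(f3, beta = 0.5, c = 1)[1, 1],
               exp(-2) * (1 - exp(-1)), tolerance = 1e-12)

  expect_error(vesselnessSingleScale(f3, beta = 0), "beta")

  # equivalence with a scalar per-pixel oracle on random eigenvalue fields
  set.seed(9)
  for (rep in 1:3) {
    l2 <- matrix(rnorm(32 * 32), 32, 32)
    l1 <- l2 * runif(32 * 32)  # guarantees |l1| <= |l2|
    fld <- list(lambda1 = l1, lambda2 = l2)
    mine <- vesselnessSingleScale(fld, beta = 0.7, c = 0.9)
    orc <- frangiOracle(l1, l2, beta = 0.7, cc = 0.9)
    expect_lt(max(abs(mine - orc)), 1e-12)
    expect_true(all(mine[l2 > 0] == 0))
    expect_true(all(mine >= 0 & mine <= 1))
  }
})

test_that("multi-scale response takes the pointwise max and selects scale", {
  set.seed(11)
  img <- matrix(runif(64 * 64), 64, 64)
  p1 <- vesselnessParams(2, 2, 1L)
  ms <- multiscaleVesselness(img, p1)
  ss <- vesselnessSingleScale(hessianEigen(img, 2), beta = 0.5, c = "auto")
  expect_equal(ms$v, ss, tolerance = 1e-12)

  # adding scales never decreases the response
  mA <- multiscaleVesselness(img, vesselnessParams(1, 2, 2L))
  mB <- multiscaleVesselness(img, vesselnessParams(1, 4, 3L))  # adds sigma 4
  expect_true(all(mB$v >= mA$v - 1e-12))

  # winning scale at a Gaussian ridge centre matches a dense-grid brute force
  n <- 81L
  for (a in c(2, 3)) {
    ridge <- matrix(rep(exp(-((seq_len(n) - 41)^2) / (2 * a^2)), each = n), n)
    coarse <- multiscaleVesselness(ridge, vesselnessParams(1, 8, 8L, c = 1))
    dense <- vapply(seq(1, 8, by = 0.25), function(s)
      vesselnessSingleScale(hessianEigen(ridge, s), c = 1)[41, 41],
      numeric(1))
    best <- seq(1, 8, by = 0.25)[which.max(dense)]
    ladder <- coarse$scales
    step <- max(diff(ladder))
    expect_lt(abs(coarse$scale[41, 41] - best), step + 1e-9)
  }

  # scale selectivity: winning scale on the tube centreline grows with
  # tube width (fixed c so the structureness normalization is shared
  # across scales)
  winners <- vapply(c(2, 4, 6, 8), function(wd) {
    pts <- cbind(10 + 0:120, rep(45.2, 121))
    cov <- RootBallPheno:::.rasterTube(pts, wd, 90, 140)
    img <- 0.1 + 0.8 * cov
    ms <- multiscaleVesselness(img, vesselnessParams(1, 8, 15L, c = 0.2))
    mean(ms$scale[45, 30:100])
  }, numeric(1))
  expect_true(all(diff(winners) > 0))
})

test_that("binarization yields faithful masks on synthetic scenes", {
  # degenerate inputs
  expect_warning(m0 <- binarizeMask(matrix(0, 10, 10)), "all-zero")
  expect_false(any(m0))
  expect_false(any(binarizeMask(matrix(runif(100), 10), threshold = 1.01)))

  # full segmentation chain against generator truth
  sc <- smallScene(seed = 21L, nRoots = 10L)
  band <- sc$gt@band
  rows <- (band[1] + 4):(band[2] - 4)
  enh <- enhance(sc$color, 1.4, 0.8)
  hom <- homomorphicFilter(toGray(enh)[rows, ])
  v <- multiscaleVesselness(hom, vesselnessParams(1, 6, 6L))
  mask <- binarizeMask(v, minArea = 30L, hysteresisLow = 0.5)
  mask <- refineRootMask(mask, hom)
  gtm <- sc$gt@rootMask[rows, ]
  expect_gte(sum(mask & gtm) / sum(mask | gtm), 0.75)
  expect_true(all(v$v >= 0 & v$v <= 1))
})
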