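# Synthetic root-ball scenes with analytic ground truth.
#
# The generator emulates the capture rig: a plug-seedling root ball (a
# vertical cylinder) photographed in front of a high-texture fiducial
# curtain, with four overlapping views related by known homographies.
# Roots are smooth random-walk tubes of per-root constant width drawn with
# sub-pixel anti-aliasing over speckled substrate; ground truth uses the
# analytic centreline geometry, never pixel counts.

# Depth (mm, camera z) of the cylinder surface per panorama column.
# Ray through column u has horizontal slope s = (u - cx)/f; intersecting
# x = s*z with x^2 + (z - d)^2 = R^2 gives the near root below.
cylinderDepth <- function(spec, cols) {
  f <- spec@focal; d <- spec@axisDistance; R <- spec@cylinderRadius
  cx <- spec@imageSize[2] / 2 + 0.5
  s <- (cols - cx) / f
  disc <- d^2 - (1 + s^2) * (d^2 - R^2)
  if (any(disc <= 0))
    stop("view rays miss the root-ball cylinder at the panorama edge; ",
         "increase cylinderRadius or reduce image width")
  (d - sqrt(disc)) / (1 + s^2)
}

# Physical surface area (mm^2) subtended by one pixel at column u.
# With a vertical cylinder the metric determinant is row-independent:
# area = (z/f) * sqrt((z/f + s z_u)^2 + z_u^2).
cylinderPixelArea <- function(spec, cols) {
  f <- spec@focal
  cx <- spec@imageSize[2] / 2 + 0.5
  s <- (cols - cx) / f
  z <- cylinderDepth(spec, cols)
  du <- 1e-2
  zu <- (cylinderDepth(spec, cols + du) - cylinderDepth(spec, cols - du)) /
    (2 * du)
  (z / f) * sqrt((z / f + s * zu)^2 + zu^2)
}

bandRows <- function(spec) {
  margin <- (spec@imageSize[1] - spec@bandHeight) %/% 2L
  c(margin + 1L, margin + spec@bandHeight)
}

.fiducialPattern <- function(spec, dark = 0.04, light = 0.32) {
  h <- spec@imageSize[1]; w <- spec@imageSize[2]; cell <- spec@fiducialCell
  nr <- ceiling(h / cell); nc <- ceiling(w / cell)
  if (nr < 2L || nc < 2L)
    stop("fiducialCell leaves fewer than 2 cells per side")
  bits <- matrix(runif(nr * nc) < 0.5, nr, nc)
  big <- bits[rep(seq_len(nr), each = cell)[seq_len(h)],
              rep(seq_len(nc), each = cell)[seq_len(w)]]
  ifelse(big, light, dark)
}

#' Generate the fiducial background pattern
#'
#' A seeded pseudo-random black/white block grid standing in for the 2-D
#' code curtain that supplies feature points for registration. Decoding is
#' never needed; only corner density matters.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param dark,light the two gray levels in [0, 1].
#' @return H x W gray matrix.
#' @export
generateFiducialBackground <- function(spec, dark = 0.04, light = 0.32) {
  validObject(spec)
  withr::with_seed(spec@seed, .fiducialPattern(spec, dark, light))
}

# Smooth random-walk centreline of unit steps, reflected at the box walls.
# Surface roots of a plug run along the plug wall, so headings are drawn
# near-horizontal (either direction) in the unrolled panorama, with mild
# directional wander; isotropic walks would cross far more than real roots.
.walkCentreline <- function(nSteps, box, turnSd = 0.03) {
  x <- runif(1, box[3] + 5, box[4] - 5)
  y <- runif(1, box[1] + 5, box[2] - 5)
  theta <- sample(c(0, pi), 1L) + runif(1, -pi / 4, pi / 4)
  pts <- matrix(NA_real_, nSteps + 1L, 2L)
  pts[1L, ] <- c(x, y)
  for (i in seq_len(nSteps)) {
    theta <- theta + rnorm(1, 0, turnSd)
    nx <- x + cos(theta); ny <- y + sin(theta)
    if (nx < box[3] || nx > box[4]) { theta <- pi - theta; nx <- x + cos(theta) }
    if (ny < box[1] || ny > box[2]) { theta <- -theta; ny <- y + sin(theta) }
    x <- nx; y <- ny
    pts[i + 1L, ] <- c(x, y)
  }
  pts
}

# Rasterize one tube with butt caps and round joins: per unit segment,
# pixels within the clamped-projection perpendicular distance get
# sub-pixel coverage clamp(w/2 + 0.5 - d, 0, 1); interior vertices stamp
# discs so bends leave no wedge gaps. The coverage >= 0.5 set is exactly
# the set of pixel centres inside the tube, so its count is an unbiased
# area estimate at any orientation.
.rasterTube <- function(pts, width, h, w) {
  rad <- ceiling(width / 2 + 1.5)
  off <- expand.grid(dy = -rad:rad, dx = -rad:rad)
  cov <- matrix(0, h, w)
  n <- nrow(pts) - 1L
  stamp <- function(px, py, d) {
    ok <- px >= 1 & px <= w & py >= 1 & py <= h
    if (!any(ok)) return(invisible())
    idx <- (px[ok] - 1) * h + py[ok]
    c0 <- pmin(pmax(width / 2 + 0.5 - d[ok], 0), 1)
    cov[idx] <<- pmax(cov[idx], c0)
  }
  for (i in seq_len(n)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    mx <- round((a[1] + b[1]) / 2); my <- round((a[2] + b[2]) / 2)
    px <- mx + off$dx; py <- my + off$dy
    abx <- b[1] - a[1]; aby <- b[2] - a[2]
    t <- ((px - a[1]) * abx + (py - a[2]) * aby) / (abx^2 + aby^2)
    inSeg <- t >= 0 & t <= 1
    dx <- px - (a[1] + t * abx); dy <- py - (a[2] + t * aby)
    stamp(px[inSeg], py[inSeg], sqrt(dx^2 + dy^2)[inSeg])
    if (i > 1L) {  # round join where the polyline turns at vertex a
      p0 <- pts[i - 1L, ]
      turn <- abs((a[1] - p0[1]) * aby - (a[2] - p0[2]) * abx)
      if (turn > 1e-9) {
        vx <- round(a[1]) + off$dx; vy <- round(a[2]) + off$dy
        stamp(vx, vy, sqrt((vx - a[1])^2 + (vy - a[2])^2))
      }
    }
  }
  cov
}

#' Generate a synthetic root-ball panorama with ground truth
#'
#' Draws \code{nRoots} smooth random-walk tubes of per-root constant width
#' over speckled substrate inside the root-ball band, surrounds the band
#' with the fiducial pattern, attaches the cylinder depth model, and
#' returns full analytic ground truth. Fixing the seed makes the output
#' byte-identical.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return list with \code{color} (H x W x 3), \code{depth} (mm),
#'   \code{intrinsics}, and \code{gt} (\linkS4class{GroundTruth}).
#' @export
generateRootScene <- function(spec) {
  validObject(spec)
  h <- spec@imageSize[1]; w <- spec@imageSize[2]
  band <- bandRows(spec)
  withr::with_seed(spec@seed, {
    gray <- .fiducialPattern(spec)
    color <- array(0, c(h, w, 3L))
    # dim bluish-gray curtain
    color[, , 1] <- gray * 0.9; color[, , 2] <- gray; color[, , 3] <- gray * 1.1
    # substrate: dark brown base with bright perlite-like speckle
    bh <- spec@bandHeight
    base <- 0.16 + 0.05 * matrix(runif(bh * w), bh, w)
    spk <- matrix(runif(bh * w) < spec@speckleDensity, bh, w)
    base[spk] <- runif(sum(spk), 0.4, 0.7)
    base <- blurGray(base, 0.6)
    # roots
    cov <- matrix(0, h, w)
    skel <- matrix(FALSE, h, w)
    nr <- spec@nRoots
    lenPx <- if (nr > 0) round(runif(nr, 150, 280)) else integer(0)
    widPx <- if (nr > 0) runif(nr, spec@widthRange[1], spec@widthRange[2])
             else numeric(0)
    box <- c(band[1] + 3, band[2] - 3, 6, w - 5)  # ymin ymax xmin xmax
    for (i in seq_len(nr)) {
      pts <- .walkCentreline(lenPx[i], box)
      cov <- pmax(cov, .rasterTube(pts, widPx[i], h, w))
      ij <- unique(cbind(round(pts[, 2]), round(pts[, 1])))
      skel[ij] <- TRUE
    }
    rows <- band[1]:band[2]
    # dark occlusion gap between the plug silhouette and the curtain:
    # keeps the background-removal component filter honest and mimics the
    # ToF dropout at the depth discontinuity
    gap <- 16L
    gapRows <- c((band[1] - gap):(band[1] - 1L),
                 (band[2] + 1L):(band[2] + gap))
    gapRows <- gapRows[gapRows >= 1L & gapRows <= h]
    for (k in 1:3) {
      ch <- color[, , k]
      ch[gapRows, ] <- 0.05
      ch[rows, ] <- base * c(1.05, 0.92, 0.7)[k]
      color[, , k] <- ch
    }
    rootCol <- spec@rootIntensity * c(1.0, 0.95, 0.8)
    for (k in 1:3) color[, , k] <- clamp01((1 - cov) * color[, , k] +
                                           cov * rootCol[k])
    # depth: curtain plane outside the band, cylinder inside
    depth <- matrix(spec@backgroundDepth, h, w)
    depth[gapRows, ] <- 0  # invalid: occlusion boundary dropout
    depth[rows, ] <- matrix(cylinderDepth(spec, seq_len(w)), length(rows), w,
                            byrow = TRUE)
    # analytic ground truth under the mean-pixel-scale convention
    sPix <- mean(cylinderPixelArea(spec, seq_len(w))) / .units$mm2_per_cm2
    lPix <- sqrt(sPix)
    lenCm <- sum(lenPx) * lPix
    areaCm2 <- sum(lenPx * widPx) * sPix
    meanD <- if (lenCm > 0) areaCm2 / lenCm * .units$um_per_cm else 0
    mask <- cov >= 0.5
    intr <- c(fx = spec@focal, fy = spec@focal, cx = w / 2 + 0.5,
              cy = h / 2 + 0.5)
    gt <- new("GroundTruth", rootMask = mask, skeleton = skel,
              totalLength = lenCm, totalArea = areaCm2, meanDiameter = meanD,
              sPix = sPix, lPix = lPix,
              dsr = 100 * sum(mask[rows, ]) / (length(rows) * w),
              viewHomographies = list(), intrinsics = intr,
              band = as.integer(band),
              perRoot = data.frame(length_px = lenPx, width_px = widPx))
    list(color = color, depth = depth, intrinsics = intr, gt = gt)
  })
}

#' Render overlapping camera views of a panorama scene
#'
#' Cuts \code{nViews} overlapping windows from the panorama and warps each
#' by a mild projective perturbation (the first view, the reference, is a
#' pure crop), adding Gaussian intensity noise. Depth is resampled
#' nearest-neighbour and carries no noise. The true view-to-panorama
#' homographies are stored in the returned ground truth.
#'
#' @param scene output of \code{\link{generateRootScene}}.
#' @param nViews number of views.
#' @param overlapFrac fractional overlap between neighbouring views,
#'   in (0, 0.5).
#' @param noiseSd additive Gaussian noise sd on [0, 1] intensities
#'   (default 2 intensity levels).
#' @param perturb logical; apply projective perturbations to views 2..n.
#' @param seed RNG seed for perturbations and noise (default: scene seed
#'   stream independent value derived from the ground truth is not used;
#'   pass explicitly for reproducibility).
#' @return list with \code{frames} (list of \linkS4class{RGBDFrame}) and
#'   \code{gt} (ground truth with \code{viewHomographies} filled in).
#' @export
renderViews <- function(scene, nViews = 4L, overlapFrac = 0.4,
                        noiseSd = 2 / 255, perturb = TRUE, seed = 1L) {
  stopifnot(overlapFrac > 0, overlapFrac < 0.5, nViews >= 2L)
  color <- scene$color; depth <- scene$depth
  h <- nrow(depth); w <- ncol(depth)
  vw <- ceiling(w / (nViews - (nViews - 1) * overlapFrac))
  offs <- round(seq(0, w - vw, length.out = nViews))
  gt <- scene$gt
  frames <- vector("list", nViews)
  Hs <- vector("list", nViews)
  withSeedIfGiven(seed, {
    for (i in seq_len(nViews)) {
      Ht <- diag(3); Ht[1, 3] <- offs[i]  # view -> panorama translation
      if (perturb && i > 1L) {
        ang <- runif(1, -0.015, 0.015); sc <- 1 + runif(1, -0.01, 0.01)
        g <- runif(1, -1.5e-5, 1.5e-5); hh <- runif(1, -1.5e-5, 1.5e-5)
        P <- rbind(c(cos(ang) * sc, -sin(ang), 0),
                   c(sin(ang), cos(ang) * sc, 0),
                   c(g, hh, 1))
        ctr <- rbind(c(1, 0, vw / 2), c(0, 1, h / 2), c(0, 0, 1))
        Ht <- Ht %*% ctr %*% P %*% solve(ctr)
      }
      Hs[[i]] <- normalizeHomography(Ht)
      # view(x) = panorama(H x): warp panorama by H^-1 onto the view grid
      vcol <- warpImage(color, solve(Ht), c(h, vw))
      vdep <- warpImage(depth, solve(Ht), c(h, vw), interp = "nearest")
      vcol[is.na(vcol)] <- 0
      vdep[is.na(vdep)] <- 0
      if (noiseSd > 0)
        vcol <- clamp01(vcol + array(rnorm(length(vcol), 0, noiseSd),
                                     dim(vcol)))
      intr <- scene$intrinsics
      intr["cx"] <- intr["cx"] - offs[i]
      frames[[i]] <- RGBDFrame(vcol, vdep, intr)
    }
  })
  gt@viewHomographies <- Hs
  validObject(gt)
  list(frames = frames, gt = gt)
}

#' Generate a paired regression dataset
#'
#' Draws predictor values x uniformly over a positive range and responses
#' y = slope * x + intercept + Gaussian noise, emulating paired
#' surface-root vs total-root measurements used to fit allometric models.
#'
#' @param n sample size (>= 3).
#' @param slope,intercept true coefficients.
#' @param noiseSd response noise standard deviation.
#' @param seed RNG seed.
#' @param xRange range of the uniform predictor.
#' @return data.frame with columns x and y.
#' @export
generateRegressionDataset <- function(n, slope, intercept, noiseSd,
                                      seed = 1L, xRange = c(5, 30)) {
  if (n < 3L) stop("n must be >= 3")
  withr::with_seed(as.integer(seed), {
    x <- runif(n, xRange[1], xRange[2])
    y <- slope * x + intercept + rnorm(n, 0, noiseSd)
    data.frame(x = x, y = y)
  })
}
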