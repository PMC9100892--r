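# View registration: Harris corners on the fiducial background, adaptive
# non-maximal suppression, normalized patch descriptors, ratio-test
# matching with cross-check, RANSAC homography estimation, and
# feathered compositing of the four views into one panorama.

sobelX <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
sobelY <- t(sobelX)

#' Detect Harris corners with adaptive non-maximal suppression
#'
#' Harris corner response on the luma image, local-maximum extraction with
#' sub-pixel quadratic refinement, then ANMS: each corner's suppression
#' radius is its distance to the nearest strictly stronger corner, and the
#' \code{anmsN} corners with the largest radii are kept, giving a spatially
#' well-distributed set.
#'
#' @param img gray matrix or RGB array in [0, 1].
#' @param maxCorners cap on raw local maxima considered (strongest first).
#' @param quality minimum response as a fraction of the strongest response.
#' @param anmsN number of corners returned after ANMS.
#' @param sigmaI integration (structure tensor) Gaussian sd, px.
#' @param k Harris sensitivity constant.
#' @return data.frame with columns x, y (sub-pixel), response, radius;
#'   zero rows for featureless images.
#' @export
detectCorners <- function(img, maxCorners = 2000L, quality = 0.01,
                          anmsN = 500L, sigmaI = 2, k = 0.04) {
  gray <- toGray(img)
  gx <- convolve2d(gray, sobelX)
  gy <- convolve2d(gray, sobelY)
  g <- gaussKernel1d(sigmaI); K <- outer(g, g)
  sxx <- convolve2d(gx * gx, K)
  syy <- convolve2d(gy * gy, K)
  sxy <- convolve2d(gx * gy, K)
  R <- (sxx * syy - sxy^2) - k * (sxx + syy)^2
  rmax <- max(R)
  if (!is.finite(rmax) || rmax <= 1e-12)
    return(data.frame(x = numeric(0), y = numeric(0),
                      response = numeric(0), radius = numeric(0)))
  # strict 3x3 local maxima, excluding a 2-px border
  Rm <- as.matrix(EBImage::dilate(EBImage::Image(R - min(R)),
                                  matrix(1, 3, 3))) + min(R)
  loc <- which(R >= Rm - 1e-15 & R > quality * rmax, arr.ind = TRUE)
  loc <- loc[loc[, 1] > 2 & loc[, 1] < nrow(R) - 1 &
             loc[, 2] > 2 & loc[, 2] < ncol(R) - 1, , drop = FALSE]
  if (nrow(loc) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      response = numeric(0), radius = numeric(0)))
  resp <- R[loc]
  ord <- order(resp, decreasing = TRUE)
  ord <- head(ord, maxCorners)
  loc <- loc[ord, , drop = FALSE]; resp <- resp[ord]
  # sub-pixel refinement: 1-D quadratic fit through the response peak
  refine <- function(rm1, r0, rp1) {
    den <- rm1 - 2 * r0 + rp1
    d <- ifelse(abs(den) > 1e-12, 0.5 * (rm1 - rp1) / den, 0)
    pmin(pmax(d, -0.5), 0.5)
  }
  i <- loc[, 1]; j <- loc[, 2]
  dy <- refine(R[cbind(i - 1, j)], resp, R[cbind(i + 1, j)])
  dx <- refine(R[cbind(i, j - 1)], resp, R[cbind(i, j + 1)])
  x <- j + dx; y <- i + dy
  .anmsSelect(x, y, resp, anmsN)
}

# Adaptive non-maximal suppression: each corner's suppression radius is the
# distance to the nearest strictly stronger corner (Inf for the global
# maximum); the n corners with the largest radii are returned, sorted by
# radius. Input must be sorted by decreasing response.
.anmsSelect <- function(x, y, resp, n) {
  m <- length(x)
  radius <- rep(Inf, m)
  if (m > 1L) {
    d2 <- as.matrix(stats::dist(cbind(x, y)))^2
    for (a in 2:m) radius[a] <- sqrt(min(d2[a, 1:(a - 1)]))
  }
  keep <- head(order(radius, decreasing = TRUE), n)
  out <- data.frame(x = x[keep], y = y[keep], response = resp[keep],
                    radius = radius[keep])
  out[order(out$radius, decreasing = TRUE), , drop = FALSE]
}

# 8 x 8 normalized intensity patch sampled with stride `spacing` from the
# blurred image (classic MOPS-style descriptor). Rows of the result are
# descriptors; corners too close to the border get NA descriptors.
extractDescriptors <- function(img, corners, patch = 8L, spacing = 5L,
                               blurSigma = 2) {
  gray <- blurGray(toGray(img), blurSigma)
  offs <- (seq_len(patch) - (patch + 1) / 2) * spacing
  grid <- expand.grid(dx = offs, dy = offs)
  D <- matrix(NA_real_, nrow(corners), patch * patch)
  for (i in seq_len(nrow(corners))) {
    v <- bilinearSample(gray, corners$x[i] + grid$dx, corners$y[i] + grid$dy)
    if (anyNA(v)) next
    s <- sd(v)
    D[i, ] <- if (s > 1e-8) (v - mean(v)) / s else v * 0
  }
  D
}

#' Match corners between two frames
#'
#' Nearest-neighbour matching of normalized patch descriptors with a
#' Lowe-style ratio test and a symmetric cross-check.
#'
#' @param imgA,imgB images (gray or RGB).
#' @param cornersA,cornersB corner data frames from
#'   \code{\link{detectCorners}}.
#' @param ratio ratio-test threshold (best / second-best distance).
#' @return data.frame with xA, yA, xB, yB; raises an
#'   \code{insufficientOverlap} condition when fewer than 4 matches survive.
#' @export
matchDescriptors <- function(imgA, cornersA, imgB, cornersB, ratio = 0.8) {
  DA <- extractDescriptors(imgA, cornersA)
  DB <- extractDescriptors(imgB, cornersB)
  okA <- which(!is.na(DA[, 1])); okB <- which(!is.na(DB[, 1]))
  fail <- function() stop(structure(class = c("insufficientOverlap", "error",
                                              "condition"),
    list(message = "fewer than 4 descriptor matches between frames",
         call = sys.call(-1))))
  if (length(okA) < 4L || length(okB) < 4L) fail()
  DA <- DA[okA, , drop = FALSE]; DB <- DB[okB, , drop = FALSE]
  # squared distances ||a||^2 + ||b||^2 - 2 a.b
  d2 <- outer(rowSums(DA^2), rowSums(DB^2), "+") - 2 * DA %*% t(DB)
  bestAB <- max.col(-d2)
  bestBA <- max.col(-t(d2))
  passRatio <- vapply(seq_len(nrow(d2)), function(a) {
    o <- sort(d2[a, ], partial = min(2L, ncol(d2)))
    ncol(d2) < 2L || o[1] < ratio^2 * o[2]
  }, logical(1))
  sel <- which(passRatio & bestBA[bestAB] == seq_len(nrow(d2)))
  if (length(sel) < 4L) fail()
  ia <- okA[sel]; ib <- okB[bestAB[sel]]
  data.frame(xA = cornersA$x[ia], yA = cornersA$y[ia],
             xB = cornersB$x[ib], yB = cornersB$y[ib])
}

#' Estimate a homography from matches with RANSAC
#'
#' Minimal 4-point DLT hypotheses scored by reprojection error, followed by
#' a least-squares DLT refit on the inliers of the best model. The returned
#' homography maps (xA, yA) onto (xB, yB).
#'
#' @param matches data.frame with columns xA, yA, xB, yB.
#' @param reprojTol inlier reprojection tolerance, px.
#' @param maxIter RANSAC iteration cap (adaptive early stop).
#' @param seed RNG seed making the inlier set reproducible.
#' @param confidence adaptive-termination confidence.
#' @return list with \code{H} (normalized 3 x 3) and \code{inliers}
#'   (logical vector over matches); raises \code{homographyFailure} when no
#'   model reaches 4 inliers.
#' @export
estimateHomography <- function(matches, reprojTol = 2, maxIter = 2000L,
                               seed = 1L, confidence = 0.999) {
  n <- nrow(matches)
  fail <- function(msg) stop(structure(class = c("homographyFailure", "error",
                                                 "condition"),
    list(message = msg, call = sys.call(-1))))
  if (n < 4L) fail("need at least 4 matches for a homography")
  src <- as.matrix(matches[, c("xA", "yA")])
  dst <- as.matrix(matches[, c("xB", "yB")])
  reprojErr <- function(H) {
    p <- applyHomography(H, src)
    sqrt(rowSums((p - dst)^2))
  }
  bestIn <- rep(FALSE, n); bestCount <- 0L
  withSeedIfGiven(seed, {
    it <- 0L; need <- maxIter
    while (it < min(need, maxIter)) {
      it <- it + 1L
      idx <- sample.int(n, 4L)
      Hc <- tryCatch(dltHomography(src[idx, ], dst[idx, ]),
                     error = function(e) NULL)
      if (is.null(Hc) || abs(det(Hc)) < 1e-12) next
      inl <- reprojErr(Hc) <= reprojTol
      if (sum(inl) > bestCount) {
        bestCount <- sum(inl); bestIn <- inl
        ratio <- bestCount / n
        need <- if (ratio >= 1) it else
          ceiling(log(1 - confidence) / log(1 - ratio^4))
      }
    }
  })
  if (bestCount < 4L) fail("RANSAC found no model with >= 4 inliers")
  H <- dltHomography(src[bestIn, , drop = FALSE], dst[bestIn, , drop = FALSE])
  inl <- reprojErr(H) <= reprojTol
  if (sum(inl) >= 4L) {
    H <- dltHomography(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
  } else inl <- bestIn
  list(H = normalizeHomography(H), inliers = inl)
}

# Feathering weight: distance to the nearest frame border, in pixels.
.borderWeight <- function(h, w) {
  r <- pmin(seq_len(h), h + 1 - seq_len(h))
  c <- pmin(seq_len(w), w + 1 - seq_len(w))
  outer(r, c, pmin)
}

#' Composite registered views into one panorama
#'
#' Warps every frame into the reference frame's plane and blends them:
#' colour by centre-weighted feathering (weights fall off towards each
#' frame's border), depth by nearest-neighbour warping with first-valid-wins
#' overlap resolution, so no depth values are interpolated between frames.
#' The output canvas is the union of the warped footprints; its intrinsics
#' are the reference frame's with the principal point shifted to canvas
#' coordinates.
#'
#' @param frames list of \linkS4class{RGBDFrame}.
#' @param homographies list of 3 x 3 matrices mapping each frame into the
#'   reference frame's plane.
#' @param referenceIndex which frame defines the output plane.
#' @return list with \code{frame} (stitched \linkS4class{RGBDFrame}) and
#'   \code{offset} c(x, y): canvas (1,1) sits at reference-plane coordinate
#'   (1 + x, 1 + y).
#' @export
compositeViews <- function(frames, homographies, referenceIndex = 1L) {
  stopifnot(length(frames) == length(homographies), length(frames) >= 1L)
  for (H in homographies)
    if (abs(det(H)) < 1e-12) stop("non-invertible homography")
  corners <- do.call(rbind, lapply(seq_along(frames), function(i) {
    d <- dim(depthData(frames[[i]]))
    applyHomography(homographies[[i]],
                    cbind(c(1, d[2], 1, d[2]), c(1, 1, d[1], d[1])))
  }))
  x0 <- floor(min(corners[, 1])); y0 <- floor(min(corners[, 2]))
  x1 <- ceiling(max(corners[, 1])); y1 <- ceiling(max(corners[, 2]))
  offset <- c(x0 - 1, y0 - 1)
  cw <- x1 - x0 + 1L; ch <- y1 - y0 + 1L
  acc <- array(0, c(ch, cw, 3L)); wsum <- matrix(0, ch, cw)
  depth <- matrix(0, ch, cw)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]; H <- homographies[[i]]
    wc <- warpImage(colorData(fr), H, c(ch, cw), offset)
    d <- dim(depthData(fr))
    wt <- warpImage(.borderWeight(d[1], d[2]), H, c(ch, cw), offset)
    wt[is.na(wt) | is.na(wc[, , 1])] <- 0
    for (k in 1:3) {
      ck <- wc[, , k]; ck[is.na(ck)] <- 0
      acc[, , k] <- acc[, , k] + wt * ck
    }
    wsum <- wsum + wt
    wd <- warpImage(depthData(fr), H, c(ch, cw), offset, interp = "nearest")
    wd[is.na(wd)] <- 0
    fill <- depth == 0 & wd > 0
    depth[fill] <- wd[fill]
  }
  for (k in 1:3) acc[, , k] <- ifelse(wsum > 0, acc[, , k] / wsum, 0)
  intr <- intrinsics(frames[[referenceIndex]])
  intr["cx"] <- intr["cx"] - offset[1]
  intr["cy"] <- intr["cy"] - offset[2]
  list(frame = RGBDFrame(clamp01(acc), depth, intr), offset = offset)
}

# Guided re-matching: project every corner of A into B through H, pair
# with the nearest corner of B within tol, and refit by least-squares DLT.
# Descriptor matching only ever pairs corners that survived ANMS in both
# frames; guided matching recovers the rest, shrinking the estimate's
# noise by sqrt(n).
.guidedRefit <- function(H, cornersA, cornersB, tol = 1.2, iters = 2L) {
  B <- as.matrix(cornersB[, c("x", "y")])
  A <- as.matrix(cornersA[, c("x", "y")])
  for (it in seq_len(iters)) {
    p <- applyHomography(H, A)
    nn <- vapply(seq_len(nrow(p)), function(i) {
      d2 <- (B[, 1] - p[i, 1])^2 + (B[, 2] - p[i, 2])^2
      j <- which.min(d2)
      if (d2[j] <= tol^2) j else NA_integer_
    }, integer(1))
    ok <- !is.na(nn)
    if (sum(ok) < 8L) return(H)
    H <- dltHomography(A[ok, , drop = FALSE], B[nn[ok], , drop = FALSE])
  }
  H
}

# Direct (photometric) refinement of a pairwise homography mapping A's
# pixels into B: Gauss-Newton on the 8 projective parameters minimizing
# the intensity SSD over the overlap. Corners only constrain the estimate
# where corners exist; every overlap pixel constrains this one.
.photometricRefit <- function(grayA, grayB, H, iters = 20L, stride = 2L,
                              margin = 8L, presmooth = 1.5) {
  if (presmooth > 0) {  # damps resampling-induced model mismatch
    grayA <- blurGray(grayA, presmooth)
    grayB <- blurGray(grayB, presmooth)
  }
  hA <- nrow(grayA); wA <- ncol(grayA)
  xs <- seq(margin, wA - margin, by = stride)
  ys <- seq(margin, hA - margin, by = stride)
  x <- rep(xs, each = length(ys)); y <- rep(ys, times = length(xs))
  a <- as.vector(grayA[cbind(y, x)])
  # gradient images of B (central differences)
  hB <- nrow(grayB); wB <- ncol(grayB)
  gxB <- grayB; gxB[, 2:(wB - 1)] <- (grayB[, 3:wB] - grayB[, 1:(wB - 2)]) / 2
  gyB <- grayB; gyB[2:(hB - 1), ] <- (grayB[3:hB, ] - grayB[1:(hB - 2), ]) / 2
  p <- as.vector(t(H))[1:8]  # row-major, p9 = 1
  for (it in seq_len(iters)) {
    D <- p[7] * x + p[8] * y + 1
    u <- (p[1] * x + p[2] * y + p[3]) / D
    v <- (p[4] * x + p[5] * y + p[6]) / D
    b <- bilinearSample(grayB, u, v)
    ok <- !is.na(b)
    if (sum(ok) < 500L) return(H)
    gx <- bilinearSample(gxB, u[ok], v[ok])
    gy <- bilinearSample(gyB, u[ok], v[ok])
    xo <- x[ok]; yo <- y[ok]; Do <- D[ok]; uo <- u[ok]; vo <- v[ok]
    r <- b[ok] - a[ok]
    J <- cbind(gx * xo / Do, gx * yo / Do, gx / Do,
               gy * xo / Do, gy * yo / Do, gy / Do,
               -(gx * uo + gy * vo) * xo / Do,
               -(gx * uo + gy * vo) * yo / Do)
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) return(H)
    p <- p - as.vector(step)
    if (max(abs(step)) < 1e-10) break
  }
  normalizeHomography(matrix(c(p, 1), 3, 3, byrow = TRUE))
}

#' Register a view sequence to a reference view
#'
#' Chains pairwise registrations i <-> i+1 into homographies mapping every
#' frame onto the reference frame's plane. Each pairwise estimate is
#' descriptor matching + RANSAC followed by guided re-matching over all
#' detected corners.
#'
#' @param frames list of \linkS4class{RGBDFrame} in capture order.
#' @param referenceIndex index of the reference frame.
#' @param anmsN corners kept per frame.
#' @param reprojTol RANSAC inlier tolerance, px.
#' @param seed RANSAC seed.
#' @return list of 3 x 3 homographies (identity at the reference).
#' @export
registerViews <- function(frames, referenceIndex = 1L, anmsN = 800L,
                          reprojTol = 2, seed = 1L) {
  nf <- length(frames)
  corners <- lapply(frames, function(f)
    detectCorners(colorData(f), maxCorners = 4000L, anmsN = anmsN))
  pairH <- vector("list", nf)  # H mapping frame i -> frame i-1
  for (i in seq_len(nf - 1L)) {
    m <- matchDescriptors(colorData(frames[[i + 1L]]), corners[[i + 1L]],
                          colorData(frames[[i]]), corners[[i]])
    H <- estimateHomography(m, reprojTol = reprojTol, seed = seed + i)$H
    H <- .guidedRefit(H, corners[[i + 1L]], corners[[i]])
    pairH[[i + 1L]] <- .photometricRefit(toGray(colorData(frames[[i + 1L]])),
                                         toGray(colorData(frames[[i]])),
                                         normalizeHomography(H))
  }
  out <- vector("list", nf)
  out[[referenceIndex]] <- diag(3)
  if (referenceIndex < nf)
    for (i in (referenceIndex + 1L):nf)
      out[[i]] <- normalizeHomography(out[[i - 1L]] %*% pairH[[i]])
  if (referenceIndex > 1L)
    for (i in (referenceIndex - 1L):1L)
      out[[i]] <- normalizeHomography(out[[i + 1L]] %*% solve(pairH[[i + 1L]]))
  out
}

#' Extract a rectangular region of interest
#'
#' Crops colour and depth and shifts the principal point by the crop
#' offset so the pinhole model stays valid in ROI coordinates.
#'
#' @param frame an \linkS4class{RGBDFrame}.
#' @param roi c(x, y, w, h): top-left corner (1-based) and size.
#' @return cropped \linkS4class{RGBDFrame}.
#' @export
extractROI <- function(frame, roi) {
  d <- dim(depthData(frame))
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (w < 1 || h < 1) stop("empty ROI rectangle")
  if (x < 1 || y < 1 || x + w - 1 > d[2] || y + h - 1 > d[1])
    stop("ROI outside the canvas")
  rows <- y:(y + h - 1); cols <- x:(x + w - 1)
  intr <- intrinsics(frame)
  intr["cx"] <- intr["cx"] - (x - 1)
  intr["cy"] <- intr["cy"] - (y - 1)
  RGBDFrame(colorData(frame)[rows, cols, , drop = FALSE],
            depthData(frame)[rows, cols], intr)
}

#' Depth-to-colour alignment hook
#'
#' Extension point for vendor depth-to-colour registration. Frames produced
#' by this package (and by the synthetic generator) are already
#' co-registered, so this is the identity; replace it when ingesting raw
#' sensor pairs.
#'
#' @param frame an \linkS4class{RGBDFrame}.
#' @return the frame, unchanged.
#' @export
alignDepth <- function(frame) frame
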