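# Independent brute-force oracles used to derive expected values. These
# deliberately share no code with the implementation they check.

# Shi-Tomasi-style corner response: central-difference gradients, 5 x 5
# box-summed structure tensor, smaller eigenvalue.
cornerResponseOracle <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (gray[, 3:w] - gray[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (gray[3:h, ] - gray[1:(h - 2), ]) / 2
  boxsum <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
    out <- matrix(0, h, w)
    for (i in 3:(h - 2)) for (j in 3:(w - 2)) {
      out[i, j] <- cs[j + 2, i + 2] - cs[j - 3 + 1, i + 2] -
        cs[j + 2, i - 3 + 1] + cs[j - 3 + 1, i - 3 + 1]
    }
    out
  }
  a <- boxsum(gx * gx); b <- boxsum(gy * gy); c <- boxsum(gx * gy)
  tr <- (a + b) / 2
  tr - sqrt(((a - b) / 2)^2 + c^2)  # min eigenvalue
}

# Count strict 5 x 5 local maxima above a relative threshold.
countCornerMaxima <- function(resp, rel = 0.05) {
  h <- nrow(resp); w <- ncol(resp)
  thr <- rel * max(resp)
  n <- 0L
  for (i in 4:(h - 3)) for (j in 4:(w - 3)) {
    v <- resp[i, j]
    if (v > thr && v >= max(resp[(i - 2):(i + 2), (j - 2):(j + 2)]))
      n <- n + 1L
  }
  n
}

# Greedy ANMS oracle: plain loops, strictly-stronger rule.
anmsOracle <- function(x, y, resp, n) {
  m <- length(x)
  r <- rep(Inf, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (resp[j] > resp[i]) {
        d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
        if (d < r[i]) r[i] <- d
      }
    }
  }
  ord <- order(r, decreasing = TRUE)[seq_len(n)]
  list(idx = ord, radius = r[ord])
}

# Scalar per-pixel evaluation of the vesselness response from eigenvalue
# fields, written as naive double loops.
frangiOracle <- function(l1, l2, beta, cc) {
  out <- matrix(0, nrow(l1), ncol(l1))
  for (i in seq_len(nrow(l1))) for (j in seq_len(ncol(l1))) {
    a <- l1[i, j]; b <- l2[i, j]
    if (b > 0) { out[i, j] <- 0; next }
    rb <- if (b != 0) abs(a) / abs(b) else 0
    s2 <- a^2 + b^2
    out[i, j] <- exp(-rb^2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
  }
  out
}

# Brute-force binary erosion/dilation by an arbitrary structuring element
# (logical matrix with odd dimensions, origin at the centre).
morphOracle <- function(mask, se, op = c("erode", "dilate")) {
  op <- match.arg(op)
  h <- nrow(mask); w <- ncol(mask)
  rk <- (nrow(se) - 1L) %/% 2L; ck <- (ncol(se) - 1L) %/% 2L
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- logical(0)
    for (di in -rk:rk) for (dj in -ck:ck) {
      if (!se[di + rk + 1L, dj + ck + 1L]) next
      ii <- i + di; jj <- j + dj
      inside <- ii >= 1 && ii <= h && jj >= 1 && jj <= w
      vals <- c(vals, if (inside) mask[ii, jj] else FALSE)
    }
    out[i, j] <- if (op == "erode") all(vals) else any(vals)
  }
  out
}

# Brute-force 3 x 3 binary median (majority) filter, zero-padded.
medianOracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0L
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj])
        s <- s + 1L
    }
    out[i, j] <- s >= 5L
  }
  out
}

# Euclidean 8-connected chain length oracle by explicit link loops.
chainLengthOracle <- function(skel, lPix) {
  idx <- which(skel, arr.ind = TRUE)
  total <- 0
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= nrow(skel) && jj >= 1 && jj <= ncol(skel) &&
          skel[ii, jj])
        total <- total + sqrt(sum(d^2))
    }
  }
  total * lPix
}

# Deterministic correspondence set from a known homography, with optional
# uniform outliers appended.
simulateMatches <- function(H, n = 80L, nOut = 0L, seed = 1L,
                            range = c(10, 200)) {
  withr::with_seed(seed, {
    src <- cbind(runif(n, range[1], range[2]), runif(n, range[1], range[2]))
    dst <- applyHomography(H, src)
    if (nOut > 0L) {
      so <- cbind(runif(nOut, range[1], range[2]),
                  runif(nOut, range[1], range[2]))
      do <- cbind(runif(nOut, range[1], range[2]),
                  runif(nOut, range[1], range[2]))
      src <- rbind(src, so); dst <- rbind(dst, do)
    }
    data.frame(xA = src[, 1], yA = src[, 2], xB = dst[, 1], yB = dst[, 2])
  })
}

# Small scene used by several tests (fast to draw and segment).
smallScene <- function(seed = 1L, nRoots = 8L, ...) {
  generateRootScene(sceneSpec(nRoots = nRoots, seed = seed, ...))
}
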