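# Topology-preserving 8-connected thinning (Zhang & Suen's two-subiteration
# scheme), vectorized over the whole grid. Produces the 1-px-wide skeleton
# whose pixel count feeds the calibrated length estimate.

#' Thin a binary mask to its skeleton
#'
#' Iterative two-pass thinning that preserves 8-connectivity and endpoints,
#' yielding a one-pixel-wide centreline.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical skeleton matrix.
#' @export
thinMask <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask > 0)
  h <- nrow(m); w <- ncol(m)
  core <- cbind(rep(2:(h - 1L), times = w - 2L),
                rep(2:(w - 1L), each = h - 2L))
  shift <- function(di, dj) m[cbind(core[, 1] + di, core[, 2] + dj)]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p <- m[core]
      p2 <- shift(-1L, 0L); p3 <- shift(-1L, 1L); p4 <- shift(0L, 1L)
      p5 <- shift(1L, 1L); p6 <- shift(1L, 0L); p7 <- shift(1L, -1L)
      p8 <- shift(0L, -1L); p9 <- shift(-1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ring <- cbind(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- rowSums(ring[, 1:8, drop = FALSE] == 0L &
                   ring[, 2:9, drop = FALSE] == 1L)
      cond <- p == 1L & B >= 2L & B <= 6L & A == 1L
      if (pass == 1L) {
        cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        m[core[cond, , drop = FALSE]] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] > 0L
  .pruneRedundant(out)
}

# Reduce the parallel-thinning output to a minimal 8-connected skeleton.
# Zhang-Suen leaves staircase pixels at intermediate orientations; here
# any non-endpoint pixel whose neighbours remain 8-connected within its
# 3 x 3 neighbourhood after removal (a "simple" pixel) is deleted
# sequentially in row-major order, iterating to a fixed point. The local
# flood-fill test preserves topology exactly; endpoints (single
# neighbour) are never deleted, so branch lengths are not eaten.
.pruneRedundant <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- skel
  connectedAfterRemoval <- function(nb) {
    idx <- which(nb)
    if (length(idx) < 2L) return(TRUE)
    coords <- cbind((idx - 1L) %% 3L + 1L, (idx - 1L) %/% 3L + 1L)
    reached <- rep(FALSE, length(idx)); reached[1L] <- TRUE
    repeat {
      added <- FALSE
      for (a in which(!reached)) {
        for (b in which(reached)) {
          if (max(abs(coords[a, ] - coords[b, ])) <= 1L) {
            reached[a] <- TRUE; added <- TRUE; break
          }
        }
      }
      if (!added) break
    }
    all(reached)
  }
  repeat {
    changed <- FALSE
    cand <- which(pad, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!pad[i, j]) next
      nb <- pad[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
      nb[2, 2] <- FALSE
      if (sum(nb) >= 2L && connectedAfterRemoval(nb)) {
        pad[i, j] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1L), 2:(w + 1L)]
}
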