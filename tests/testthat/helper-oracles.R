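## Independent oracles and fixture builders used across the suite. These
## deliberately avoid the package's own code paths where they serve as a
## cross-check.

## A random histogram with support on at least two of maxL gray levels.
rndHistogram <- function(maxL = 16L) {
  L <- sample(3:maxL, 1)
  counts <- rpois(L, lambda = sample(c(1, 5, 50), 1))
  if (sum(counts > 0) < 2) {
    ix <- sample(L, 2)
    counts[ix] <- counts[ix] + 1L
  }
  grayHistogram(counts, nLevels = L)
}

## Exhaustive-scan oracle: every fixed point of the midpoint-of-class-means
## map, computed from raw weighted sums (independent of classMeans).
## Returns the threshold values t with floor(t) == the split that made them.
oracleFixedPoints <- function(counts) {
  L <- length(counts)
  F <- seq_len(L) - 1L
  nz <- which(counts > 0) - 1L
  fmin <- min(nz); fmax <- max(nz)
  fixed <- numeric(0)
  for (j in fmin:(fmax - 1L)) {
    left <- F <= j
    dl <- sum(counts[left] * F[left]) / sum(counts[left])
    dr <- sum(counts[!left] * F[!left]) / sum(counts[!left])
    t <- (dl + dr) / 2
    jj <- min(max(floor(t), fmin), fmax - 1L)   # clamped split bucket
    if (jj == j) fixed <- c(fixed, t)
  }
  fixed
}

## A random sparse 3-D logical mask.
rndMask <- function(d = c(8L, 8L, 4L), p = 0.3) {
  array(runif(prod(d)) < p, d)
}

## Brute-force erosion oracle: literal neighborhood check, loops and all.
bruteErode <- function(m, offsets) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    keep <- TRUE
    for (r in seq_len(nrow(offsets))) {
      xx <- x + offsets[r, 1]; yy <- y + offsets[r, 2]; zz <- z + offsets[r, 3]
      inb <- xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] &&
             zz >= 1 && zz <= d[3]
      if (!inb || !m[xx, yy, zz]) { keep <- FALSE; break }
    }
    out[x, y, z] <- keep
  }
  out
}

## Build a mask whose per-slice foreground counts follow `pixels`, with
## unit in-plane spacing so slice areas equal the counts.
maskFromProfile <- function(pixels, nx = 8L, ny = 8L) {
  m <- array(FALSE, c(nx, ny, length(pixels)))
  for (z in seq_along(pixels)) {
    if (pixels[z] > 0) m[, , z][seq_len(pixels[z])] <- TRUE
  }
  BinaryMask(m, spacing = c(1, 1, 1))
}
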