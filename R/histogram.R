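#' Gray-level histogram of a quantized volume
#'
#' Counts voxels per gray level F in \{0, ..., L-1\}. The volume must
#' already be quantized to integer levels (see [quantizeVolume()]); the
#' histogram is the substrate of the iterative threshold selection.
#'
#' @param volume A [CTVolume-class] with integer values in \code{[0, L-1]}.
#' @param nLevels Number of gray levels L (default 256).
#' @param ... Unused.
#' @return A [GrayHistogram-class].
#' @examples
#' v <- CTVolume(array(c(0, 255, 255, 255), c(2, 2, 1)))
#' h <- computeHistogram(v)
#' grayMin(h); grayMax(h)
#' @rdname computeHistogram
#' @export
setMethod("computeHistogram", "CTVolume", function(volume, nLevels = 256L, ...) {
  computeHistogram(volume@values, nLevels = nLevels)
})

#' @rdname computeHistogram
#' @export
setMethod("computeHistogram", "array", function(volume, nLevels = 256L, ...) {
  L <- as.integer(nLevels)
  v <- as.vector(volume)
  if (length(v) == 0L) stop("empty input")
  if (any(v != round(v)) || any(v < 0) || any(v > L - 1L))
    stop("volume is not quantized to integer gray levels in [0, L-1]")
  counts <- tabulate(as.integer(v) + 1L, nbins = L)
  nz <- which(counts > 0L)
  new("GrayHistogram", counts = as.numeric(counts), nLevels = L,
      grayMin = nz[1] - 1L, grayMax = nz[length(nz)] - 1L)
})

#' @rdname accessors
#' @export
setMethod("grayCounts", "GrayHistogram", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("grayMin", "GrayHistogram", function(x) x@grayMin)

#' @rdname accessors
#' @export
setMethod("grayMax", "GrayHistogram", function(x) x@grayMax)

#' @rdname accessors
#' @export
setMethod("nGrayLevels", "GrayHistogram", function(x) x@nLevels)

setMethod("show", "GrayHistogram", function(object) {
  cat(sprintf("GrayHistogram: %g voxels over %d levels, support [%d, %d]\n",
              sum(object@counts), object@nLevels,
              object@grayMin, object@grayMax))
})

#' Build a histogram directly from level counts
#'
#' Convenience constructor used by tests and simulations: supply counts per
#' gray level rather than a volume.
#'
#' @param counts Non-negative integer counts; \code{counts[F + 1]} is the
#'   count at gray level F.
#' @param nLevels Number of gray levels; defaults to \code{length(counts)}.
#' @return A [GrayHistogram-class].
#' @export
grayHistogram <- function(counts, nLevels = length(counts)) {
  L <- as.integer(nLevels)
  counts <- c(as.numeric(counts), numeric(L - length(counts)))
  nz <- which(counts > 0)
  if (length(nz) == 0L) stop("empty input")
  new("GrayHistogram", counts = counts, nLevels = L,
      grayMin = nz[1] - 1L, grayMax = nz[length(nz)] - 1L)
}

#' Initial threshold: midpoint of the gray-level support
#'
#' The iteration starts from the mean of the extreme gray values,
#' \eqn{k_0 = (F_{max} + F_{min}) / 2}.
#'
#' @param hist A [GrayHistogram-class].
#' @return The initial threshold (gray-level units, possibly half-integer).
#' @export
initialThreshold <- function(hist) {
  stopifnot(is(hist, "GrayHistogram"))
  (hist@grayMin + hist@grayMax) / 2
}

#' Class-mean gray values on either side of a threshold
#'
#' Splits the histogram at \code{floor(k)}: the lower class covers levels
#' \eqn{F = 0..\lfloor k \rfloor}, the upper class
#' \eqn{F = \lfloor k \rfloor + 1 .. L-1}, and returns the count-weighted
#' mean gray value of each class.
#'
#' @param hist A [GrayHistogram-class].
#' @param k Threshold (gray-level units).
#' @return Named numeric: \code{dLeft}, \code{dRight}.
#' @examples
#' h <- grayHistogram(replace(numeric(256), c(11, 201), 5)) # mass at 10, 200
#' classMeans(h, 100)  # (10, 200)
#' @export
classMeans <- function(hist, k) {
  stopifnot(is(hist, "GrayHistogram"))
  j <- floor(k)                       # split: levels <= j vs > j
  F <- seq_len(hist@nLevels) - 1L
  left <- F <= j
  nL <- sum(hist@counts[left]); nR <- sum(hist@counts[!left])
  if (nL == 0) stop("degenerate split: lower class is empty")
  if (nR == 0) stop("degenerate split: upper class is empty")
  c(dLeft  = sum(hist@counts[left] * F[left]) / nL,
    dRight = sum(hist@counts[!left] * F[!left]) / nR)
}

#' Iterative threshold selection
#'
#' Finds the global segmentation threshold as the fixed point of the
#' midpoint-of-class-means map: starting from
#' \eqn{k_0 = (F_{max}+F_{min})/2}, repeat
#' \eqn{k_{i+1} = (D_L(k_i) + D_R(k_i)) / 2} where \eqn{D_L, D_R} are the
#' mean gray values of the two classes split at \eqn{k_i}, until the
#' iterates agree exactly (\eqn{k_{i+1} = k_i}). Exact agreement is always
#' reached: both class means are nondecreasing in the split level, so the
#' induced map on integer split levels is monotone and its orbit settles on
#' a fixed split, after which the iterate repeats bit-identically. A
#' positive \code{tol} loosens the stopping rule to
#' \eqn{|k_{i+1} - k_i| \le tol} for callers who want fewer iterations. If
#' a split would empty one class, it is clamped to the nearest gray level
#' keeping both classes nonempty.
#'
#' @param hist A [GrayHistogram-class] with \code{grayMin < grayMax}.
#' @param maxIter Iteration cap (default 100).
#' @param tol Convergence tolerance in gray levels (default 0: exact
#'   agreement of successive iterates).
#' @return A [ThresholdTrace-class]; \code{finalThreshold()} gives the
#'   converged threshold.
#' @examples
#' h <- grayHistogram(replace(numeric(256), c(11, 201), 5))
#' finalThreshold(iterateThreshold(h))  # 105
#' @export
iterateThreshold <- function(hist, maxIter = 100L, tol = 0) {
  stopifnot(is(hist, "GrayHistogram"))
  if (hist@grayMin >= hist@grayMax)
    stop("histogram support is a single gray level; no threshold to select")
  clamp <- function(k) {
    ## keep floor(k) in [grayMin, grayMax - 1] so both classes are nonempty
    j <- floor(k)
    if (j < hist@grayMin) k <- hist@grayMin
    else if (j > hist@grayMax - 1L) k <- hist@grayMax - 1L
    k
  }
  k <- initialThreshold(hist)
  ks <- dl <- dr <- numeric(0)
  converged <- FALSE
  final <- NA_real_
  for (i in seq_len(maxIter)) {
    k <- clamp(k)
    m <- classMeans(hist, k)
    ks <- c(ks, k); dl <- c(dl, m[["dLeft"]]); dr <- c(dr, m[["dRight"]])
    kNext <- (m[["dLeft"]] + m[["dRight"]]) / 2
    if (abs(kNext - k) <= tol) {
      kNext <- clamp(kNext)
      mN <- classMeans(hist, kNext)
      ks <- c(ks, kNext); dl <- c(dl, mN[["dLeft"]]); dr <- c(dr, mN[["dRight"]])
      converged <- TRUE
      final <- kNext
      break
    }
    k <- kNext
  }
  trace <- new("ThresholdTrace", thresholds = ks, dLeft = dl, dRight = dr,
               converged = converged, finalThreshold = final)
  if (!converged) {
    cond <- simpleError(sprintf(
      "threshold iteration did not converge within %d iterations", maxIter))
    cond$trace <- trace
    class(cond) <- c("airwayCT_nonconvergence", class(cond))
    stop(cond)
  }
  trace
}

#' @rdname accessors
#' @export
setMethod("finalThreshold", "ThresholdTrace", function(x) x@finalThreshold)

#' @rdname accessors
#' @export
setMethod("thresholdIterates", "ThresholdTrace", function(x) x@thresholds)

#' @rdname accessors
#' @export
setMethod("isConverged", "ThresholdTrace", function(x) x@converged)

setMethod("show", "ThresholdTrace", function(object) {
  cat(sprintf("ThresholdTrace: %d iterates, %s, final threshold %g\n",
              length(object@thresholds),
              if (object@converged) "converged" else "NOT converged",
              object@finalThreshold))
})
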