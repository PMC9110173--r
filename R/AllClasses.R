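#' @import methods
NULL

## Canonical vocabulary used throughout the package. Order matters: regions
## run cranial -> caudal, and region ranges are half-open on slice indices.
.airwayPhases <- c("calm_breathing", "deep_end_inspiration",
                   "deep_end_expiration", "muller")
.airwayRegions <- c("nasopharyngeal", "posterior_palatal",
                    "retrolingual", "laryngopharyngeal")

#' Respiratory phases and airway regions
#'
#' Canonical labels used by the package: the four respiratory phases under
#' which the upper airway is scanned, and the four contiguous anatomical
#' regions (cranial to caudal) into which the airway is partitioned.
#'
#' @return A character vector of labels.
#' @examples
#' airwayPhases()
#' airwayRegions()
#' @export
airwayPhases <- function() .airwayPhases

#' @rdname airwayPhases
#' @export
airwayRegions <- function() .airwayRegions

#' CTVolume: a 3-D attenuation volume
#'
#' Container for one CT acquisition: a 3-D scalar array of attenuation
#' values with voxel spacing (in-plane x, in-plane y, axial z, in mm), an
#' optional respiratory-phase label and subject identifier. Axial slice 1
#' is the most cranial slice.
#'
#' @slot values 3-D numeric array of attenuation values.
#' @slot spacing Numeric length-3 voxel spacing in mm \code{(dx, dy, dz)}.
#' @slot phase Respiratory phase label, one of \code{airwayPhases()} or
#'   \code{NA} for a phase-less volume.
#' @slot subjectID Subject identifier or \code{NA}.
#' @export
setClass("CTVolume",
  representation(values = "array", spacing = "numeric",
                 phase = "character", subjectID = "character"),
  prototype(spacing = c(0.5, 0.5, 2.5), phase = NA_character_,
            subjectID = NA_character_))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive values (mm)")
  if (length(object@phase) != 1L ||
      (!is.na(object@phase) && !object@phase %in% .airwayPhases))
    msg <- c(msg, sprintf("'phase' must be NA or one of: %s",
                          paste(.airwayPhases, collapse = ", ")))
  if (length(object@subjectID) != 1L)
    msg <- c(msg, "'subjectID' must be a single identifier")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a segmentation mask congruent with a volume
#'
#' A logical 3-D array marking foreground voxels, carrying the voxel
#' spacing of the volume it was derived from so that physical areas can be
#' computed. Foreground denotes the airway lumen (low attenuation) under
#' the default segmentation polarity.
#'
#' @slot values Logical 3-D array; \code{TRUE} marks foreground.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot foregroundMeaning Free-text tag describing what foreground is.
#' @export
setClass("BinaryMask",
  representation(values = "array", spacing = "numeric",
                 foregroundMeaning = "character"),
  prototype(spacing = c(0.5, 0.5, 2.5),
            foregroundMeaning = "airway lumen (low attenuation)"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L || !is.logical(object@values))
    msg <- c(msg, "'values' must be a logical 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' GrayHistogram: gray-level counts of a quantized volume
#'
#' Integer counts per gray level F in \{0, ..., L-1\}; the substrate of the
#' iterative threshold selection. \code{counts[F + 1]} is the number of
#' voxels with quantized value F.
#'
#' @slot counts Numeric vector of length L of non-negative integer counts.
#' @slot nLevels Number of gray levels L.
#' @slot grayMin,grayMax Minimum / maximum gray level with nonzero count.
#' @export
setClass("GrayHistogram",
  representation(counts = "numeric", nLevels = "integer",
                 grayMin = "integer", grayMax = "integer"))

setValidity("GrayHistogram", function(object) {
  msg <- character()
  L <- object@nLevels
  if (length(object@counts) != L)
    msg <- c(msg, "'counts' must have length nLevels")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "'counts' must be non-negative integers")
  if (sum(object@counts) < 1)
    msg <- c(msg, "histogram is empty")
  fmin <- object@grayMin; fmax <- object@grayMax
  if (!(fmin >= 0L && fmin <= fmax && fmax <= L - 1L))
    msg <- c(msg, "require 0 <= grayMin <= grayMax <= L-1")
  if (length(msg) == 0L &&
      (object@counts[fmin + 1L] <= 0 || object@counts[fmax + 1L] <= 0))
    msg <- c(msg, "grayMin/grayMax must carry nonzero counts")
  if (length(msg)) msg else TRUE
})

#' ThresholdTrace: the iterates of the threshold selection
#'
#' Records every threshold iterate together with the foreground/background
#' class-mean gray values at that iterate, whether the iteration converged,
#' and the final segmentation threshold.
#'
#' @slot thresholds Numeric vector of threshold iterates (gray levels),
#'   starting at the initial midpoint threshold.
#' @slot dLeft,dRight Class-mean gray values (lower / upper class) computed
#'   at each iterate; same length as \code{thresholds}.
#' @slot converged Logical flag.
#' @slot finalThreshold The converged threshold, rounded to the nearest
#'   0.5 gray level.
#' @export
setClass("ThresholdTrace",
  representation(thresholds = "numeric", dLeft = "numeric",
                 dRight = "numeric", converged = "logical",
                 finalThreshold = "numeric"))

setValidity("ThresholdTrace", function(object) {
  msg <- character()
  n <- length(object@thresholds)
  if (n < 1L) msg <- c(msg, "empty trace")
  if (length(object@dLeft) != n || length(object@dRight) != n)
    msg <- c(msg, "class-mean vectors must match the number of iterates")
  if (length(msg)) msg else TRUE
})

#' StructuringElement: neighborhood for morphological erosion
#'
#' A set of integer voxel offsets defining the neighborhood B of the
#' erosion operator. The default elements are symmetric (B = -B) and
#' contain the origin.
#'
#' @slot offsets Integer matrix with one row per offset and columns
#'   \code{(dx, dy, dz)}.
#' @seealso [structuringElement()]
#' @export
setClass("StructuringElement", representation(offsets = "matrix"))

setValidity("StructuringElement", function(object) {
  off <- object@offsets
  msg <- character()
  if (!is.numeric(off) || ncol(off) != 3L || any(off != round(off)))
    msg <- c(msg, "'offsets' must be an integer matrix with 3 columns")
  else if (!any(rowSums(off == 0) == 3L))
    msg <- c(msg, "element must contain the origin offset")
  if (length(msg)) msg else TRUE
})

#' AirwayLandmarks: axial boundaries of the airway regions
#'
#' The five axial slice indices (1-based, slice 1 most cranial) that bound
#' the four airway regions: the nasopharyngeal dome, the hard-palate plane,
#' the lower end of the soft palate, the upper edge of the epiglottis and
#' the upper edge of the hyoid bone. They must be strictly increasing.
#'
#' @slot zDome,zHardPalate,zSoftPalateLower,zEpiglottisUpper,zHyoidUpper
#'   Integer axial slice indices, strictly ordered cranial to caudal.
#' @export
setClass("AirwayLandmarks",
  representation(zDome = "integer", zHardPalate = "integer",
                 zSoftPalateLower = "integer", zEpiglottisUpper = "integer",
                 zHyoidUpper = "integer"))

setValidity("AirwayLandmarks", function(object) {
  z <- c(object@zDome, object@zHardPalate, object@zSoftPalateLower,
         object@zEpiglottisUpper, object@zHyoidUpper)
  if (length(z) != 5L || any(is.na(z)))
    return("all five landmarks must be single integers")
  if (any(diff(z) <= 0))
    return("landmarks out of order: require zDome < zHardPalate < zSoftPalateLower < zEpiglottisUpper < zHyoidUpper")
  if (z[1] < 1L) return("landmarks must be positive slice indices")
  TRUE
})

#' PhantomSpec: parameters of the synthetic airway phantom
#'
#' Describes a piecewise-tubular upper-airway phantom: a dark air column
#' (lumen) running axially through bright soft tissue, with a per-region,
#' per-phase lumen radius, a mild within-region waist placing the narrowest
#' section mid-region, a sinusoidal centerline wobble, and additive
#' Gaussian noise.
#'
#' @slot shape Integer length-3 array dimensions \code{(nx, ny, nz)}.
#' @slot spacing Numeric length-3 voxel spacing in mm; the default axial
#'   step is 2.5 mm (5 mm slices reconstructed at 2.5 mm spacing).
#' @slot landmarks An [AirwayLandmarks-class] giving the region boundaries;
#'   the lumen spans \code{[zDome, zHyoidUpper)}.
#' @slot radii 4 x 4 numeric matrix of lumen radii in mm, rows =
#'   \code{airwayRegions()}, columns = \code{airwayPhases()}.
#' @slot tissueIntensity,airIntensity Gray values of soft tissue and of the
#'   air column on the quantized 0..255 scale; air must be darker.
#' @slot noiseSD Standard deviation of additive Gaussian noise (gray values).
#' @slot wobbleAmplitude,wobbleCycles Sinusoidal centerline wobble: amplitude
#'   in mm and number of cycles over the axial extent.
#' @slot waist Fractional within-region narrowing at the region midpoint
#'   (0 = perfect cylinder per region).
#' @slot seed RNG seed making the phantom reproducible.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 landmarks = "AirwayLandmarks", radii = "matrix",
                 tissueIntensity = "numeric", airIntensity = "numeric",
                 noiseSD = "numeric", wobbleAmplitude = "numeric",
                 wobbleCycles = "numeric", waist = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 4L))
    msg <- c(msg, "'shape' must be 3 dimensions of at least 4")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be strictly positive")
  r <- object@radii
  if (!identical(dim(r), c(4L, 4L)) || any(r <= 0))
    msg <- c(msg, "'radii' must be a positive 4x4 matrix (region x phase)")
  if (object@airIntensity >= object@tissueIntensity)
    msg <- c(msg, "lumen must be darker than tissue (airIntensity < tissueIntensity)")
  if (object@noiseSD < 0) msg <- c(msg, "'noiseSD' must be >= 0")
  if (object@waist < 0 || object@waist >= 1)
    msg <- c(msg, "'waist' must be in [0, 1)")
  lm <- object@landmarks
  if (lm@zHyoidUpper > object@shape[3] + 1L)
    msg <- c(msg, "landmarks exceed the axial extent")
  ## tube must fit in-plane, including wobble and the widest radius
  halfx <- object@shape[1] * object@spacing[1] / 2
  halfy <- object@shape[2] * object@spacing[2] / 2
  if (max(r) + object@wobbleAmplitude >= min(halfx, halfy))
    msg <- c(msg, "tube radius (plus wobble) exceeds the volume bounds")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of the synthetic two-group cohort
#'
#' Describes a case/control cohort: per-group normal distributions for the
#' continuous metrics (demographics, cardiac dimensions, spirometry), a
#' per-group male proportion, and per-region mean collapse degrees from
#' which per-subject collapse values are drawn (truncated normal).
#'
#' @slot nPerGroup Subjects per group.
#' @slot continuous Data frame with columns \code{metric}, \code{testMean},
#'   \code{testSD}, \code{controlMean}, \code{controlSD}.
#' @slot maleProportion Named numeric length-2, male proportion in the
#'   \code{test} and \code{control} groups.
#' @slot collapseMean 4 x 2 matrix of mean collapse degrees, rows =
#'   \code{airwayRegions()}, columns = \code{c("test", "control")}.
#' @slot collapseSD Common SD of the per-subject collapse draws.
#' @slot seed RNG seed.
#' @export
setClass("CohortSpec",
  representation(nPerGroup = "integer", continuous = "data.frame",
                 maleProportion = "numeric", collapseMean = "matrix",
                 collapseSD = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 2L) msg <- c(msg, "'nPerGroup' must be >= 2")
  need <- c("metric", "testMean", "testSD", "controlMean", "controlSD")
  if (!all(need %in% names(object@continuous)))
    msg <- c(msg, "'continuous' lacks required columns")
  else if (any(object@continuous$testSD <= 0) ||
           any(object@continuous$controlSD <= 0))
    msg <- c(msg, "SDs must be > 0")
  if (any(object@maleProportion < 0) || any(object@maleProportion > 1))
    msg <- c(msg, "'maleProportion' must lie in [0, 1]")
  if (!identical(dim(object@collapseMean), c(4L, 2L)))
    msg <- c(msg, "'collapseMean' must be 4 regions x 2 groups")
  if (object@collapseSD <= 0) msg <- c(msg, "'collapseSD' must be > 0")
  if (length(msg)) msg else TRUE
})

#' ComparisonResult: one two-sample comparison
#'
#' The outcome of a single group comparison: the statistic, its degrees of
#' freedom (if defined), the two-sided p-value, and a significance flag at
#' the chosen alpha.
#'
#' @slot metric Name of the compared quantity.
#' @slot method Test used (e.g. "pooled t", "Wilcoxon rank-sum").
#' @slot statistic Test statistic value.
#' @slot df Degrees of freedom, \code{NA} where not applicable.
#' @slot p Two-sided p-value.
#' @slot alpha Significance level.
#' @slot significant \code{TRUE} iff \code{p < alpha}.
#' @export
setClass("ComparisonResult",
  representation(metric = "character", method = "character",
                 statistic = "numeric", df = "numeric", p = "numeric",
                 alpha = "numeric", significant = "logical"),
  prototype(metric = NA_character_, alpha = 0.05))

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "'p' must lie in [0, 1]")
  if (!is.na(object@p) &&
      !identical(object@significant, unname(object@p < object@alpha)))
    msg <- c(msg, "'significant' must equal p < alpha")
  if (length(msg)) msg else TRUE
})
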