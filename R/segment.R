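#' Binarize a quantized volume at a threshold
#'
#' Splits the voxels into two classes at the segmentation threshold. Under
#' the default polarity (\code{"dark"}) the foreground is the airway lumen:
#' air is low-attenuation, so voxels with value \code{<= threshold} are
#' foreground. Set \code{polarity = "bright"} to segment the tissue class
#' instead. The two classes always partition the volume exactly.
#'
#' @param volume A [CTVolume-class] (quantized).
#' @param threshold Segmentation threshold in gray-level units.
#' @param polarity \code{"dark"} (foreground = values below or at the
#'   threshold, the air column) or \code{"bright"}.
#' @param ... Unused.
#' @return A [BinaryMask-class] congruent with the volume.
#' @rdname binarize
#' @export
setMethod("binarize", "CTVolume",
  function(volume, threshold, polarity = c("dark", "bright"), ...) {
    polarity <- match.arg(polarity)
    fg <- if (polarity == "dark") volume@values <= threshold
          else volume@values > threshold
    BinaryMask(fg, spacing = volume@spacing,
               foregroundMeaning = if (polarity == "dark")
                 "airway lumen (low attenuation)" else "soft tissue (high attenuation)")
  })

#' Segmentation parameters
#'
#' Collects the tunable parameters of the segmentation pipeline with their
#' defaults. The quantization window defaults to the 8-bit scale
#' \code{[0, 255]} (an identity mapping for volumes already on that scale);
#' set it explicitly to window Hounsfield-unit data.
#'
#' @param grayLevels Number of gray levels L after quantization.
#' @param windowLow,windowHigh Attenuation window mapped linearly onto
#'   \code{0..L-1}; values outside are clipped.
#' @param polarity Foreground polarity for [binarize()].
#' @param erosionElement Structuring element type for [erodeMask()].
#' @param erosionIterations Number of erosion passes.
#' @param connectivity Component connectivity for [extractLumen()] (26 or 6).
#' @param component Which component to keep: \code{"largest"} or a voxel
#'   coordinate.
#' @param maxIter,tol Iteration cap and convergence tolerance (gray levels)
#'   for [iterateThreshold()].
#' @return A named list of validated parameters.
#' @export
segmentationParams <- function(grayLevels = 256L, windowLow = 0,
                               windowHigh = 255,
                               polarity = c("dark", "bright"),
                               erosionElement = c("cross", "square", "cross3d"),
                               erosionIterations = 1L, connectivity = 26L,
                               component = "largest",
                               maxIter = 100L, tol = 0) {
  if (windowLow >= windowHigh) stop("inverted window: windowLow >= windowHigh")
  list(grayLevels = as.integer(grayLevels), windowLow = windowLow,
       windowHigh = windowHigh, polarity = match.arg(polarity),
       erosionElement = match.arg(erosionElement),
       erosionIterations = as.integer(erosionIterations),
       connectivity = as.integer(connectivity), component = component,
       maxIter = as.integer(maxIter), tol = tol)
}

#' Segment the airway lumen of a CT volume
#'
#' The full single-threshold segmentation pipeline: quantize the volume to
#' L gray levels, build the gray-level histogram, select the global
#' threshold by the iterative class-means rule, binarize, erode the
#' foreground boundary once to suppress peripheral background interference,
#' and keep the single connected component that is the airway lumen. The
#' result is fully deterministic given the volume and parameters.
#'
#' @param volume A raw [CTVolume-class].
#' @param params A list from [segmentationParams()].
#' @param ... Unused.
#' @return A list with elements \code{mask} (the lumen [BinaryMask-class])
#'   and \code{trace} (the [ThresholdTrace-class]).
#' @examples
#' spec <- phantomSpec(noiseSD = 0)
#' vol <- generatePhantom(spec, "deep_end_expiration")
#' seg <- segmentAirway(vol)
#' finalThreshold(seg$trace)  # 120 for the 40/200 two-level phantom
#' @rdname segmentAirway
#' @export
setMethod("segmentAirway", "CTVolume",
  function(volume, params = segmentationParams(), ...) {
    q <- quantizeVolume(volume, windowLow = params$windowLow,
                        windowHigh = params$windowHigh,
                        nLevels = params$grayLevels)
    hist <- computeHistogram(q, nLevels = params$grayLevels)
    trace <- iterateThreshold(hist, maxIter = params$maxIter, tol = params$tol)
    mask <- binarize(q, finalThreshold(trace), polarity = params$polarity)
    mask <- erodeMask(mask, structuringElement(params$erosionElement),
                      iterations = params$erosionIterations)
    mask <- extractLumen(mask, seed = params$component,
                         connectivity = params$connectivity)
    list(mask = mask, trace = trace)
  })
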