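#' Read / write volumes as NIfTI
#'
#' Volumes are exchanged in NIfTI format (\code{.nii} or \code{.nii.gz}),
#' one file per respiratory phase, with voxel spacing taken from the
#' header. Writing uses a double-precision datatype so that a write/read
#' round trip preserves values and spacing bit-exactly.
#'
#' @param path File path.
#' @param phase,subjectID Labels attached to the returned volume (the
#'   NIfTI header does not carry them).
#' @return \code{readVolume}: a [CTVolume-class]. \code{writeVolume}: the
#'   path, invisibly.
#' @export
readVolume <- function(path, phase = NA_character_,
                       subjectID = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("corrupt header: pixdim does not give a positive 3-D spacing")
  vals <- array(as.numeric(img), dim(img))
  CTVolume(vals, spacing = sp[1:3], phase = phase, subjectID = subjectID)
}

#' @rdname readVolume
#' @param vol A [CTVolume-class] (or [BinaryMask-class], written as 0/1).
#' @export
writeVolume <- function(vol, path) {
  vals <- if (is(vol, "BinaryMask")) vol@values + 0 else vol@values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- voxelSpacing(vol)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Quantize a volume to discrete gray levels
#'
#' Maps the attenuation window \code{[windowLow, windowHigh]} linearly onto
#' the integer gray levels \code{0..L-1} (rounding to the nearest level,
#' halves away from the window floor via \code{round()}), clipping values
#' outside the window. The discrete histogram that drives the threshold
#' iteration is built on this scale. Monotone: \code{v1 <= v2} implies
#' \code{q(v1) <= q(v2)}.
#'
#' @param volume A [CTVolume-class].
#' @param windowLow,windowHigh Window bounds (must satisfy
#'   \code{windowLow < windowHigh}).
#' @param nLevels Number of gray levels L.
#' @param ... Unused.
#' @return A [CTVolume-class] with integer values in \code{0..L-1}.
#' @rdname quantizeVolume
#' @export
setMethod("quantizeVolume", "CTVolume",
  function(volume, windowLow = 0, windowHigh = 255, nLevels = 256L, ...) {
    if (windowLow >= windowHigh)
      stop("inverted window: windowLow >= windowHigh")
    L <- as.integer(nLevels)
    v <- pmin(pmax(volume@values, windowLow), windowHigh)
    q <- round((v - windowLow) / (windowHigh - windowLow) * (L - 1))
    dim(q) <- dim(volume@values)
    CTVolume(q, spacing = volume@spacing, phase = volume@phase,
             subjectID = volume@subjectID)
  })

#' Write a threshold trace as a JSON sidecar
#'
#' @param trace A [ThresholdTrace-class].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
writeTrace <- function(trace, path) {
  jsonlite::write_json(
    list(thresholds = trace@thresholds, d_left = trace@dLeft,
         d_right = trace@dRight, converged = trace@converged,
         final_threshold = trace@finalThreshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
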