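#' Construct a CTVolume
#'
#' @param values 3-D numeric array of attenuation values.
#' @param spacing Voxel spacing in mm \code{(dx, dy, dz)}.
#' @param phase Respiratory phase label (see [airwayPhases()]) or \code{NA}.
#' @param subjectID Optional subject identifier.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- CTVolume(array(0, c(4, 4, 2)), spacing = c(0.5, 0.5, 2.5))
#' dim(vol)
#' @export
CTVolume <- function(values, spacing = c(0.5, 0.5, 2.5),
                     phase = NA_character_, subjectID = NA_character_) {
  if (length(values) == 0L)
    stop("empty input: volume has no voxels")
  if (is.null(dim(values))) dim(values) <- c(length(values), 1L, 1L)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  new("CTVolume", values = values, spacing = as.numeric(spacing),
      phase = as.character(phase), subjectID = as.character(subjectID))
}

#' Construct a BinaryMask
#'
#' @param values Logical 3-D array, \code{TRUE} = foreground.
#' @param spacing Voxel spacing in mm.
#' @param foregroundMeaning Tag describing the foreground class.
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(values, spacing = c(0.5, 0.5, 2.5),
                       foregroundMeaning = "airway lumen (low attenuation)") {
  if (is.null(dim(values))) dim(values) <- c(length(values), 1L, 1L)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  storage.mode(values) <- "logical"
  new("BinaryMask", values = values, spacing = as.numeric(spacing),
      foregroundMeaning = foregroundMeaning)
}

#' @name accessors
#' @title Accessors for airwayCT objects
#' @description Slot accessors: voxel spacing, phase and subject labels,
#'   raw arrays, histogram fields, threshold-trace fields, structuring
#'   element offsets and landmark positions.
#' @param x An airwayCT object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "BinaryMask", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("phase", "CTVolume", function(x) x@phase)

#' @rdname accessors
#' @export
setMethod("subjectID", "CTVolume", function(x) x@subjectID)

#' @rdname accessors
#' @export
setMethod("volumeValues", "CTVolume", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("maskValues", "BinaryMask", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("foregroundCount", "BinaryMask", function(x) sum(x@values))

#' @export
setMethod("dim", "CTVolume", function(x) dim(x@values))

#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@values))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTVolume: %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  phase: %s   subject: %s\n", object@phase, object@subjectID))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask: %d x %d x %d voxels, %d foreground (%s)\n",
              d[1], d[2], d[3], sum(object@values),
              object@foregroundMeaning))
})
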