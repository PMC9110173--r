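#' @rdname computeHistogram
#' @export
setGeneric("computeHistogram", function(volume, nLevels = 256L, ...)
  standardGeneric("computeHistogram"))

#' @rdname binarize
#' @export
setGeneric("binarize", function(volume, threshold, ...)
  standardGeneric("binarize"))

#' @rdname erodeMask
#' @export
setGeneric("erodeMask", function(mask, element = structuringElement("cross"),
                                 iterations = 1L, ...)
  standardGeneric("erodeMask"))

#' @rdname extractLumen
#' @export
setGeneric("extractLumen", function(mask, seed = "largest", ...)
  standardGeneric("extractLumen"))

#' @rdname segmentAirway
#' @export
setGeneric("segmentAirway", function(volume, params = segmentationParams(), ...)
  standardGeneric("segmentAirway"))

#' @rdname quantizeVolume
#' @export
setGeneric("quantizeVolume", function(volume, windowLow = 0, windowHigh = 255,
                                      nLevels = 256L, ...)
  standardGeneric("quantizeVolume"))

#' @rdname sliceArea
#' @export
setGeneric("sliceArea", function(mask, z, ...) standardGeneric("sliceArea"))

#' @rdname regionArea
#' @export
setGeneric("regionArea", function(mask, range, summary = c("min", "mean"), ...)
  standardGeneric("regionArea"))

## ---- accessors ------------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("phase", function(x) standardGeneric("phase"))

#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("volumeValues", function(x) standardGeneric("volumeValues"))

#' @rdname accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))

#' @rdname accessors
#' @export
setGeneric("foregroundCount", function(x) standardGeneric("foregroundCount"))

#' @rdname accessors
#' @export
setGeneric("grayCounts", function(x) standardGeneric("grayCounts"))

#' @rdname accessors
#' @export
setGeneric("grayMin", function(x) standardGeneric("grayMin"))

#' @rdname accessors
#' @export
setGeneric("grayMax", function(x) standardGeneric("grayMax"))

#' @rdname accessors
#' @export
setGeneric("nGrayLevels", function(x) standardGeneric("nGrayLevels"))

#' @rdname accessors
#' @export
setGeneric("finalThreshold", function(x) standardGeneric("finalThreshold"))

#' @rdname accessors
#' @export
setGeneric("thresholdIterates", function(x) standardGeneric("thresholdIterates"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("elementOffsets", function(x) standardGeneric("elementOffsets"))

#' @rdname accessors
#' @export
setGeneric("landmarkVector", function(x) standardGeneric("landmarkVector"))
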