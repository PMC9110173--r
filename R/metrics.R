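#' Cross-sectional area of one axial slice
#'
#' Foreground voxel count in slice \code{z} times the in-plane pixel area
#' (mm^2).
#'
#' @param mask A [BinaryMask-class].
#' @param z Axial slice index (1-based).
#' @param ... Unused.
#' @return Area in mm^2.
#' @rdname sliceArea
#' @export
setMethod("sliceArea", "BinaryMask", function(mask, z, ...) {
  d <- dim(mask@values)
  z <- as.integer(z)
  if (any(z < 1L) || any(z > d[3]))
    stop(sprintf("slice index out of range 1..%d", d[3]))
  px <- mask@spacing[1] * mask@spacing[2]
  vapply(z, function(zi) sum(mask@values[, , zi]) * px, numeric(1))
})

#' Representative cross-sectional area of an airway region
#'
#' Summarizes the per-slice area profile over a half-open axial range
#' \code{[start, end)}. The default summary is the minimum: collapsibility
#' is governed by the narrowest cross-section of a segment. \code{"mean"}
#' averages the profile instead.
#'
#' @param mask A [BinaryMask-class].
#' @param range Integer \code{c(start, end)}, end-exclusive, as produced by
#'   [partitionRegions()].
#' @param summary \code{"min"} (default) or \code{"mean"}.
#' @param ... Unused.
#' @return Area in mm^2, with attribute \code{"profile"} holding the
#'   per-slice areas. If the region has no foreground on any slice the
#'   value is 0 and a warning is raised.
#' @rdname regionArea
#' @export
setMethod("regionArea", "BinaryMask",
  function(mask, range, summary = c("min", "mean"), ...) {
    summary <- match.arg(summary)
    zs <- seq.int(range[[1]], range[[2]] - 1L)
    if (length(zs) < 1L) stop("empty region range")
    profile <- sliceArea(mask, zs)
    if (all(profile == 0))
      warning("region has zero foreground on every slice")
    out <- if (summary == "min") min(profile) else mean(profile)
    attr(out, "profile") <- profile
    out
  })

#' Airway collapse degree
#'
#' The per-region collapsibility statistic: the fractional loss of
#' cross-sectional area from deep end-expiration to deep end-inspiration,
#' \deqn{(A_{exp} - A_{insp}) / A_{exp}.}
#' It is 0 when the two areas are equal, at most 1, and negative when the
#' airway widens on inspiration. It is invariant to a common rescaling of
#' both areas.
#'
#' @param areaExp End-expiratory cross-sectional area (mm^2), must be > 0.
#' @param areaInsp End-inspiratory cross-sectional area (mm^2).
#' @return Dimensionless collapse degree.
#' @examples
#' collapseDegree(100, 40)  # 0.6
#' @export
collapseDegree <- function(areaExp, areaInsp) {
  if (any(areaExp <= 0))
    stop("undefined collapse degree (zero expiratory area)")
  (areaExp - areaInsp) / areaExp
}

#' Measure one subject across respiratory phases
#'
#' Runs the segmentation pipeline on each supplied phase volume, measures
#' the representative cross-sectional area of each airway region in each
#' phase, and computes the per-region collapse degree from the deep
#' end-expiration and deep end-inspiration phases. Calm-breathing and
#' Muller volumes, when supplied, are segmented and measured but do not
#' enter the collapse formula.
#'
#' @param volumes Named list of [CTVolume-class], names from
#'   [airwayPhases()]. Must include \code{deep_end_expiration} and
#'   \code{deep_end_inspiration}; all volumes must share shape and spacing.
#' @param landmarks An [AirwayLandmarks-class] for this subject.
#' @param params Segmentation parameters ([segmentationParams()]).
#' @param summary Area summary per region, \code{"min"} or \code{"mean"}.
#' @return A list with:
#'   \describe{
#'     \item{areas}{data.frame \code{(region, phase, area_mm2)}.}
#'     \item{collapse}{data.frame \code{(region, collapse_degree)}.}
#'     \item{profiles}{per phase, per region numeric slice-area profiles.}
#'     \item{traces}{per phase [ThresholdTrace-class].}
#'   }
#' @export
measureSubject <- function(volumes, landmarks, params = segmentationParams(),
                           summary = c("min", "mean")) {
  summary <- match.arg(summary)
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  bad <- setdiff(names(volumes), .airwayPhases)
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  for (ph in c("deep_end_expiration", "deep_end_inspiration"))
    if (!ph %in% names(volumes)) stop("missing phase: ", ph)
  dims <- lapply(volumes, dim)
  sps <- lapply(volumes, voxelSpacing)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L ||
      length(unique(vapply(sps, paste, character(1), collapse = "x"))) != 1L)
    stop("mismatched geometry across phase volumes")
  ranges <- partitionRegions(landmarks)

  traces <- list(); profiles <- list()
  rows <- list()
  for (ph in names(volumes)) {
    seg <- segmentAirway(volumes[[ph]], params)
    traces[[ph]] <- seg$trace
    profiles[[ph]] <- list()
    for (rg in names(ranges)) {
      a <- suppressWarnings(regionArea(seg$mask, ranges[[rg]], summary = summary))
      profiles[[ph]][[rg]] <- attr(a, "profile")
      rows[[length(rows) + 1L]] <-
        data.frame(region = rg, phase = ph, area_mm2 = as.numeric(a))
    }
  }
  areas <- do.call(rbind, rows)
  aExp <- areas[areas$phase == "deep_end_expiration", ]
  aInsp <- areas[areas$phase == "deep_end_inspiration", ]
  collapse <- data.frame(
    region = aExp$region,
    collapse_degree = collapseDegree(
      aExp$area_mm2,
      aInsp$area_mm2[match(aExp$region, aInsp$region)]))
  list(areas = areas, collapse = collapse, profiles = profiles,
       traces = traces)
}
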