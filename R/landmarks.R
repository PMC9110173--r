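#' Construct airway landmarks
#'
#' The five axial boundaries that partition the upper airway, as 1-based
#' slice indices ordered cranial to caudal: nasopharyngeal dome, hard
#' palate plane, lower end of the soft palate, upper edge of the
#' epiglottis, upper edge of the hyoid bone.
#'
#' @param zDome,zHardPalate,zSoftPalateLower,zEpiglottisUpper,zHyoidUpper
#'   Strictly increasing axial slice indices.
#' @return An [AirwayLandmarks-class].
#' @examples
#' lm <- airwayLandmarks(1, 11, 21, 31, 41)
#' partitionRegions(lm)
#' @export
airwayLandmarks <- function(zDome, zHardPalate, zSoftPalateLower,
                            zEpiglottisUpper, zHyoidUpper) {
  new("AirwayLandmarks", zDome = as.integer(zDome),
      zHardPalate = as.integer(zHardPalate),
      zSoftPalateLower = as.integer(zSoftPalateLower),
      zEpiglottisUpper = as.integer(zEpiglottisUpper),
      zHyoidUpper = as.integer(zHyoidUpper))
}

#' @rdname accessors
#' @export
setMethod("landmarkVector", "AirwayLandmarks", function(x)
  c(zDome = x@zDome, zHardPalate = x@zHardPalate,
    zSoftPalateLower = x@zSoftPalateLower,
    zEpiglottisUpper = x@zEpiglottisUpper, zHyoidUpper = x@zHyoidUpper))

setMethod("show", "AirwayLandmarks", function(object) {
  z <- landmarkVector(object)
  cat("AirwayLandmarks (axial slice indices, cranial -> caudal):\n")
  print(z)
})

#' Partition the airway into anatomical regions
#'
#' Maps the landmarks to four contiguous, non-overlapping, half-open axial
#' slice ranges: nasopharyngeal \code{[zDome, zHardPalate)}, posterior
#' palatal \code{[zHardPalate, zSoftPalateLower)}, retrolingual
#' \code{[zSoftPalateLower, zEpiglottisUpper)} and laryngopharyngeal
#' \code{[zEpiglottisUpper, zHyoidUpper)}. Their union is exactly
#' \code{[zDome, zHyoidUpper)}.
#'
#' @param landmarks An [AirwayLandmarks-class].
#' @return A named list (one entry per region of [airwayRegions()]) of
#'   integer \code{c(start, end)} pairs, end-exclusive.
#' @export
partitionRegions <- function(landmarks) {
  stopifnot(is(landmarks, "AirwayLandmarks"))
  validObject(landmarks)   # enforces ordering -> "landmarks out of order"
  z <- unname(landmarkVector(landmarks))
  out <- lapply(seq_len(4), function(i) c(start = z[i], end = z[i + 1]))
  names(out) <- .airwayRegions
  out
}

#' Read / write a landmarks table
#'
#' Landmarks are exchanged as a small CSV or JSON file with columns
#' \code{subject_id, z_dome, z_hard_palate, z_soft_palate_lower,
#' z_epiglottis_upper, z_hyoid_upper}.
#'
#' @param path File path (\code{.csv} or \code{.json}).
#' @return A named list of [AirwayLandmarks-class], one per subject.
#' @export
readLandmarks <- function(path) {
  df <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  need <- c("subject_id", "z_dome", "z_hard_palate", "z_soft_palate_lower",
            "z_epiglottis_upper", "z_hyoid_upper")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmarks file lacks columns: ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    airwayLandmarks(df$z_dome[i], df$z_hard_palate[i],
                    df$z_soft_palate_lower[i], df$z_epiglottis_upper[i],
                    df$z_hyoid_upper[i]))
  names(out) <- df$subject_id
  out
}

#' @rdname readLandmarks
#' @param landmarks Named list of [AirwayLandmarks-class] (names = subject
#'   ids) or a single object.
#' @export
writeLandmarks <- function(landmarks, path) {
  if (is(landmarks, "AirwayLandmarks")) landmarks <- list(subject = landmarks)
  rows <- lapply(names(landmarks), function(id) {
    z <- landmarkVector(landmarks[[id]])
    data.frame(subject_id = id, z_dome = z[[1]], z_hard_palate = z[[2]],
               z_soft_palate_lower = z[[3]], z_epiglottis_upper = z[[4]],
               z_hyoid_upper = z[[5]])
  })
  df <- do.call(rbind, rows)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "columns", auto_unbox = FALSE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
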