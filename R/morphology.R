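#' Structuring elements for erosion
#'
#' Builds the neighborhood B used by [erodeMask()]. The default is a 3x3
#' in-plane cross (4-neighborhood plus origin) applied slice by slice: one
#' erosion pass then peels exactly the one-pixel boundary ring of each
#' axial cross-section. Alternatives: the full 3x3 in-plane square, a 3-D
#' 6-neighborhood cross, or custom offsets.
#'
#' @param type \code{"cross"} (in-plane 4-neighborhood), \code{"square"}
#'   (in-plane 8-neighborhood) or \code{"cross3d"} (3-D 6-neighborhood).
#' @param offsets Optional integer matrix of \code{(dx, dy, dz)} offsets
#'   overriding \code{type}; must contain the origin.
#' @return A [StructuringElement-class].
#' @examples
#' structuringElement("cross")
#' @export
structuringElement <- function(type = c("cross", "square", "cross3d"),
                               offsets = NULL) {
  if (is.null(offsets)) {
    type <- match.arg(type)
    offsets <- switch(type,
      cross = rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                    c(0, 1, 0), c(0, -1, 0)),
      square = {
        g <- expand.grid(dx = -1:1, dy = -1:1, dz = 0L)
        as.matrix(g)
      },
      cross3d = rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                      c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  }
  offsets <- matrix(as.integer(offsets), ncol = 3,
                    dimnames = list(NULL, c("dx", "dy", "dz")))
  new("StructuringElement", offsets = offsets)
}

#' @rdname accessors
#' @export
setMethod("elementOffsets", "StructuringElement", function(x) x@offsets)

setMethod("show", "StructuringElement", function(object) {
  cat(sprintf("StructuringElement: %d offsets, extent (%s)\n",
              nrow(object@offsets),
              paste(apply(object@offsets, 2, function(v)
                paste(range(v), collapse = "..")), collapse = ", ")))
})

## Shift a logical array by an integer offset; out-of-bounds reads are FALSE.
.shiftLogical <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  if (abs(dx) >= d[1] || abs(dy) >= d[2] || abs(dz) >= d[3]) return(out)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx - dx, sy - dy, sz - dz] <- m[sx, sy, sz]
  out
}

#' Morphological erosion of a binary mask
#'
#' A voxel is foreground in the output iff every offset of the structuring
#' element, applied from that voxel, lands on foreground of the input.
#' Neighbors outside the volume count as background, so masks touching the
#' border are shrunk there too. One pass with the default in-plane cross
#' removes the one-pixel boundary of each axial cross-section, suppressing
#' the peripheral background interference left by global thresholding.
#'
#' @param mask A [BinaryMask-class].
#' @param element A [StructuringElement-class]; default in-plane cross.
#' @param iterations Number of erosion passes (default 1).
#' @param ... Unused.
#' @return The eroded [BinaryMask-class].
#' @examples
#' sq <- array(FALSE, c(7, 7, 1)); sq[2:6, 2:6, 1] <- TRUE
#' foregroundCount(erodeMask(BinaryMask(sq)))  # 9: the inner 3x3 survives
#' @rdname erodeMask
#' @export
setMethod("erodeMask", "BinaryMask",
  function(mask, element = structuringElement("cross"), iterations = 1L, ...) {
    m <- mask@values
    off <- element@offsets
    ## requirement at voxel p and offset o is m[p + o]; .shiftLogical(m, o)
    ## evaluates exactly that at every p, with FALSE outside the volume
    for (it in seq_len(iterations)) {
      out <- m
      for (r in seq_len(nrow(off))) {
        if (all(off[r, ] == 0L)) next
        out <- out & .shiftLogical(m, off[r, 1], off[r, 2], off[r, 3])
        dim(out) <- dim(m)
      }
      m <- out
    }
    BinaryMask(m, spacing = mask@spacing,
               foregroundMeaning = mask@foregroundMeaning)
  })

## Label connected components of a logical 3-D array by breadth-first
## expansion on a one-voxel padded copy (the pad absorbs boundary reads).
## Returns an integer array of labels, 0 = background.
.labelComponents <- function(m, connectivity = 26L) {
  d <- dim(m)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  if (connectivity == 26L) {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  } else if (connectivity == 6L) {
    g <- data.frame(dx = c(1, -1, 0, 0, 0, 0), dy = c(0, 0, 1, -1, 0, 0),
                    dz = c(0, 0, 0, 0, 1, -1))
  } else stop("connectivity must be 26 or 6")
  offs <- g$dx + dp[1] * (g$dy + dp[2] * g$dz)
  lab <- integer(prod(dp))
  fg <- which(pad)
  todo <- logical(prod(dp)); todo[fg] <- TRUE
  id <- 0L
  for (s in fg) {
    if (!todo[s]) next
    id <- id + 1L
    lab[s] <- id; todo[s] <- FALSE
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[todo[nb]]
      if (!length(nb)) break
      lab[nb] <- id; todo[nb] <- FALSE
      frontier <- nb
    }
  }
  dim(lab) <- dp
  lab[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
}

#' Extract the airway lumen component
#'
#' Keeps exactly one connected component of the mask — the one containing a
#' seed voxel, or the largest by voxel count — and discards everything
#' else. Components are defined by 26-connectivity in 3-D by default
#' (appropriate for an obliquely oriented tubular airway). Ties in size are
#' broken deterministically by the component whose lexicographically
#' smallest \code{(x, y, z)} coordinate is smallest.
#'
#' @param mask A [BinaryMask-class] (typically after erosion).
#' @param seed Either \code{"largest"} or an integer length-3 voxel
#'   coordinate that must lie on foreground.
#' @param connectivity 26 (default) or 6.
#' @param ... Unused.
#' @return A [BinaryMask-class] with a single connected component.
#' @rdname extractLumen
#' @export
setMethod("extractLumen", "BinaryMask",
  function(mask, seed = "largest", connectivity = 26L, ...) {
    if (foregroundCount(mask) == 0L) stop("no foreground")
    lab <- .labelComponents(mask@values, connectivity = connectivity)
    if (is.character(seed)) {
      sizes <- tabulate(lab[lab > 0L])
      best <- which(sizes == max(sizes))
      if (length(best) > 1L) {
        ## tie-break: smallest lexicographic minimum (x, y, z) coordinate
        minCoord <- t(vapply(best, function(id) {
          co <- which(lab == id, arr.ind = TRUE)
          co[order(co[, 1], co[, 2], co[, 3])[1], ]
        }, numeric(3)))
        best <- best[order(minCoord[, 1], minCoord[, 2], minCoord[, 3])[1]]
      }
      keep <- best
    } else {
      seed <- as.integer(seed)
      stopifnot(length(seed) == 3L)
      keep <- lab[seed[1], seed[2], seed[3]]
      if (keep == 0L) stop("seed not in foreground")
    }
    BinaryMask(lab == keep, spacing = mask@spacing,
               foregroundMeaning = mask@foregroundMeaning)
  })
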