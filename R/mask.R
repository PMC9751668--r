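#' @include grid.R
NULL

#' Construct a structure mask
#'
#' @param grid An \code{ImageGrid}.
#' @param name Structure label.
#' @param member Logical 3D array matching the grid shape.
#' @return A \code{StructureMask}.
#' @export
structureMask <- function(grid, name, member)
  new("StructureMask", grid = grid, name = name, member = member)

#' @rdname maskVolume
#' @export
setMethod("maskVolume", "StructureMask", function(x)
  sum(x@member) * voxelVolume(x@grid) / 1000)

#' Construct a structure set
#'
#' @param grid The shared \code{ImageGrid}.
#' @param ... \code{StructureMask} objects; names default to each mask's
#'   own \code{name} slot.
#' @return A \code{StructureSet}.
#' @export
structureSet <- function(grid, ...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1]]) &&
      !is(masks[[1]], "StructureMask"))
    masks <- masks[[1]]
  nm <- names(masks)
  auto <- vapply(masks, function(m) m@name, character(1))
  if (is.null(nm)) nm <- auto else nm[!nzchar(nm)] <- auto[!nzchar(nm)]
  names(masks) <- nm
  new("StructureSet", grid = grid, masks = masks)
}

#' @rdname structureNames
#' @export
setMethod("structureNames", "StructureSet", function(x) names(x@masks))

#' Extract one structure from a set
#'
#' @param x A \code{StructureSet}.
#' @param i Structure name or index.
#' @return A \code{StructureMask}.
#' @export
setMethod("[[", "StructureSet", function(x, i) x@masks[[i]])

#' Voxelize an axis-aligned ellipsoid
#'
#' A voxel is a member iff its centre satisfies the ellipsoid inequality
#' sum(((x - c) / a)^2) <= 1.
#'
#' @param grid An \code{ImageGrid}.
#' @param center Ellipsoid centre, world mm (length 3).
#' @param semiaxes Semiaxes in mm (length 3, positive).
#' @param name Structure label for the result.
#' @return A \code{StructureMask}.
#' @export
ellipsoidMask <- function(grid, center, semiaxes, name = "ellipsoid") {
  if (any(semiaxes <= 0)) stop("ellipsoid semiaxes must be positive")
  structureMask(grid, name, ellipsoidRadius2(grid, center, semiaxes) <= 1)
}

## Squared normalized ellipsoidal radius field; separable outer sums keep
## this O(N) in memory traffic.
ellipsoidRadius2 <- function(grid, center, semiaxes) {
  dx2 <- ((axisCoords(grid, 1) - center[1]) / semiaxes[1])^2
  dy2 <- ((axisCoords(grid, 2) - center[2]) / semiaxes[2])^2
  dz2 <- ((axisCoords(grid, 3) - center[3]) / semiaxes[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Mask set algebra
#'
#' Voxel-wise union, intersection and difference of two masks on the same
#' grid.
#'
#' @param a,b \code{StructureMask}s on one grid.
#' @param name Label for the result.
#' @return A \code{StructureMask}.
#' @export
maskUnion <- function(a, b, name = a@name) {
  stopIfGridMismatch(a, b, "masks")
  structureMask(a@grid, name, a@member | b@member)
}

#' @rdname maskUnion
#' @export
maskIntersect <- function(a, b, name = a@name) {
  stopIfGridMismatch(a, b, "masks")
  structureMask(a@grid, name, a@member & b@member)
}

#' @rdname maskUnion
#' @export
maskDifference <- function(a, b, name = a@name) {
  stopIfGridMismatch(a, b, "masks")
  structureMask(a@grid, name, a@member & !b@member)
}

#' Is one mask contained in another?
#'
#' @param inner,outer \code{StructureMask}s on one grid.
#' @return \code{TRUE} iff every member voxel of \code{inner} is a member
#'   of \code{outer}.
#' @export
maskContains <- function(outer, inner) {
  stopIfGridMismatch(outer, inner, "masks")
  !any(inner@member & !outer@member)
}
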