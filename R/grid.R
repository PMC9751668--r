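#' @include AllClasses.R
NULL

#' Construct an image grid
#'
#' @param shape Voxels per axis (length 3).
#' @param spacing Voxel spacing in mm (length 3), default c(1, 1, 3) —
#'   typical in-plane 1 mm resolution with 3 mm slices.
#' @param origin World coordinate (mm) of the first voxel centre.
#' @return An \code{ImageGrid}.
#' @examples
#' imageGrid(c(64, 64, 16), spacing = c(1, 1, 3))
#' @export
imageGrid <- function(shape, spacing = c(1, 1, 3), origin = c(0, 0, 0)) {
  new("ImageGrid", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Default MR-like grid
#'
#' 256 x 256 in-plane at 1 mm with 64 slices of 3 mm, emulating a typical
#' 256-matrix MR acquisition with 3 mm slice thickness.
#'
#' @return An \code{ImageGrid}.
#' @export
defaultGrid <- function() imageGrid(c(256L, 256L, 64L), c(1, 1, 3))

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "ImageGrid", function(x) prod(x@spacing))

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "ScalarVolume", function(x) prod(x@grid@spacing))

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "StructureMask", function(x) prod(x@grid@spacing))

#' @rdname imageGridOf
#' @export
setMethod("imageGridOf", "ScalarVolume", function(x) x@grid)

#' @rdname imageGridOf
#' @export
setMethod("imageGridOf", "StructureMask", function(x) x@grid)

#' @rdname imageGridOf
#' @export
setMethod("imageGridOf", "StructureSet", function(x) x@grid)

#' Voxel-centre world coordinates along one axis
#'
#' @param grid An \code{ImageGrid}.
#' @param axis 1, 2 or 3.
#' @return Numeric vector of world mm, one per voxel.
#' @export
axisCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1) * grid@spacing[axis]
}

#' Physical extent of the grid per axis
#'
#' @param grid An \code{ImageGrid}.
#' @return Length-3 vector, mm spanned by voxel centres per axis.
#' @export
gridExtent <- function(grid) (grid@shape - 1) * grid@spacing

#' Grid centre in world coordinates
#'
#' @param grid An \code{ImageGrid}.
#' @return Length-3 vector, mm.
#' @export
gridCenter <- function(grid) grid@origin + gridExtent(grid) / 2

sameGrid <- function(a, b) {
  identical(a@shape, b@shape) &&
    isTRUE(all.equal(a@spacing, b@spacing)) &&
    isTRUE(all.equal(a@origin, b@origin))
}

stopIfGridMismatch <- function(a, b, what = "volumes") {
  ga <- if (is(a, "ImageGrid")) a else a@grid
  gb <- if (is(b, "ImageGrid")) b else b@grid
  if (!sameGrid(ga, gb))
    stop("mismatched grids between companion ", what)
  invisible(TRUE)
}

#' Construct a perfusion map
#'
#' @param grid An \code{ImageGrid}.
#' @param values 3D array of CBF values (ml/100g/min), finite, >= 0.
#' @return A \code{PerfusionMap}.
#' @export
perfusionMap <- function(grid, values)
  new("PerfusionMap", grid = grid, values = values)

#' Construct a dose grid
#'
#' @param grid An \code{ImageGrid}.
#' @param values 3D array of dose values (Gy), finite, >= 0.
#' @return A \code{DoseGrid}.
#' @export
doseGrid <- function(grid, values)
  new("DoseGrid", grid = grid, values = values)

## Evaluate an expression with a private RNG stream: the caller's
## .Random.seed is restored on exit so library code never perturbs user
## simulations.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
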