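#' @include mask.R
NULL

gridToAffine <- function(grid) {
  rbind(cbind(diag(grid@spacing), grid@origin), c(0, 0, 0, 1))
}

#' Write a volume or mask as NIfTI
#'
#' Masks are written as uint8 with a 0/1 payload; scalar volumes
#' (perfusion, dose) as float64 so values round-trip exactly. The grid
#' geometry (spacing and origin) is carried in the sform affine.
#'
#' @param x A \code{PerfusionMap}, \code{DoseGrid} or
#'   \code{StructureMask}.
#' @param path Output path ending in .nii or .nii.gz.
#' @return The path, invisibly.
#' @export
writeVolume <- function(x, path) {
  grid <- imageGridOf(x)
  if (is(x, "StructureMask")) {
    arr <- array(as.integer(x@member), dim = grid@shape)
    dt <- "uint8"
  } else {
    arr <- x@values
    dt <- "double"
  }
  img <- RNifti::asNifti(arr, datatype = dt)
  img <- RNifti::`sform<-`(img, structure(gridToAffine(grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume, dose grid or mask from NIfTI
#'
#' Grid geometry (spacing, origin) is taken from the image's xform
#' affine. Payload validation depends on \code{what}: masks must contain
#' only 0/1 (tolerance 1e-6) and perfusion/dose volumes must be finite
#' and nonnegative; offending values are named in the error.
#'
#' @param path Path to a NIfTI file.
#' @param what One of \code{"perfusion"}, \code{"dose"}, \code{"mask"}.
#' @param name Structure name when reading a mask; defaults to the file
#'   name.
#' @return A \code{PerfusionMap}, \code{DoseGrid} or
#'   \code{StructureMask}.
#' @export
readVolume <- function(path, what = c("perfusion", "dose", "mask"),
                       name = NULL) {
  what <- match.arg(what)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions")
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  origin <- xf[1:3, 4]
  grid <- imageGrid(dim(arr), spacing, origin)
  if (what == "mask") {
    off <- abs(arr) > 1e-6 & abs(arr - 1) > 1e-6
    if (any(off))
      stop("mask payload is not binary: found value(s) ",
           paste(utils::head(signif(unique(arr[off]), 4), 5), collapse = ", "))
    if (is.null(name)) name <- sub("\\.nii(\\.gz)?$", "", basename(path))
    return(structureMask(grid, name, array(arr > 0.5, dim = dim(arr))))
  }
  if (any(!is.finite(arr)))
    stop("volume contains non-finite values")
  if (any(arr < 0))
    stop(what, " volume contains negative value(s), e.g. ",
         signif(min(arr), 4), "; ",
         if (what == "perfusion") "CBF" else "dose", " must be nonnegative")
  if (what == "perfusion") perfusionMap(grid, arr) else doseGrid(grid, arr)
}
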