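#' @import methods
NULL

#' Voxel volume of a grid or gridded object
#'
#' Product of the three voxel spacings, i.e. the physical volume of one
#' voxel in cubic millimetres.
#'
#' @param x An \code{ImageGrid} or any object carrying one.
#' @return Voxel volume in mm^3.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' Image grid of a gridded object
#'
#' @param x A volume, mask or label map.
#' @return The \code{ImageGrid} the object lives on.
#' @export
setGeneric("imageGridOf", function(x) standardGeneric("imageGridOf"))

#' Structure volume in cubic centimetres
#'
#' Member voxel count times voxel volume, divided by 1000.
#'
#' @param x A \code{StructureMask}.
#' @return Volume in cm^3.
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' Names of structures in a set
#'
#' @param x A \code{StructureSet}.
#' @return Character vector of structure names.
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))
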