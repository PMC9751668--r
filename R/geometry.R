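#' @include mask.R
NULL

#' Expand a mask by a physical margin
#'
#' Isotropic margin expansion in physical millimetres on an anisotropic
#' voxel grid: an output voxel is a member iff its centre lies within
#' Euclidean distance <= margin of some member voxel centre (inclusive,
#' centre-to-centre). Implemented as exact binary dilation with the set of
#' all voxel offsets whose physical length is within the margin, evaluated
#' on a cropped bounding box for speed. If the expansion reaches the grid
#' boundary a truncation warning is raised (not an error).
#'
#' @param mask A nonempty \code{StructureMask}.
#' @param marginMM Margin in mm, >= 0.
#' @param clipTo Optional \code{StructureMask} (e.g. the brain/body
#'   outline) intersected with the result.
#' @return A \code{StructureMask}; the input is always contained in the
#'   output.
#' @examples
#' g <- imageGrid(c(11, 11, 5), c(1, 1, 3))
#' m <- array(FALSE, dim = c(11, 11, 5)); m[6, 6, 3] <- TRUE
#' sum(expandMargin(structureMask(g, "pt", m), 3)@member)  # 31 voxels
#' @export
expandMargin <- function(mask, marginMM, clipTo = NULL) {
  if (marginMM < 0 || !is.finite(marginMM)) stop("margin must be finite and >= 0")
  if (!any(mask@member)) stop("cannot expand an empty mask")
  grid <- mask@grid
  sp <- grid@spacing
  reach <- floor(marginMM / sp + 1e-9)

  idx <- which(mask@member, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - reach, 1)
  hi <- pmin(apply(idx, 2, max) + reach, grid@shape)
  sub <- mask@member[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(sub)

  out <- array(FALSE, dim = d)
  sidx <- which(sub, arr.ind = TRUE)
  m2 <- marginMM^2 + 1e-9
  for (di in -reach[1]:reach[1]) {
    for (dj in -reach[2]:reach[2]) {
      dz2 <- m2 - (di * sp[1])^2 - (dj * sp[2])^2
      if (dz2 < 0) next
      for (dk in -reach[3]:reach[3]) {
        if ((dk * sp[3])^2 > dz2) next
        sh <- cbind(sidx[, 1] + di, sidx[, 2] + dj, sidx[, 3] + dk)
        keep <- sh[, 1] >= 1 & sh[, 1] <= d[1] &
                sh[, 2] >= 1 & sh[, 2] <= d[2] &
                sh[, 3] >= 1 & sh[, 3] <= d[3]
        out[sh[keep, , drop = FALSE]] <- TRUE
      }
    }
  }

  member <- array(FALSE, dim = grid@shape)
  member[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- out
  ## detect truncation: a margin that would have extended past the grid
  touched <- any(idx[, 1] - reach[1] < 1) || any(idx[, 1] + reach[1] > grid@shape[1]) ||
             any(idx[, 2] - reach[2] < 1) || any(idx[, 2] + reach[2] > grid@shape[2]) ||
             any(idx[, 3] - reach[3] < 1) || any(idx[, 3] + reach[3] > grid@shape[3])
  if (touched && marginMM > 0)
    warning("margin expansion reaches the grid boundary; result may be truncated")
  if (!is.null(clipTo)) {
    stopIfGridMismatch(mask, clipTo, "masks")
    member <- member & clipTo@member
  }
  structureMask(grid, mask@name, member)
}

#' Derive the nested planning targets
#'
#' PTV = GTV plus \code{marginPTV} (5 mm), PTV_H = GTV_H plus
#' \code{marginPTVH} (3 mm), PTV_N = PTV minus PTV_H. Since GTV_H is
#' contained in GTV and the boost margin does not exceed the PTV margin,
#' PTV_H is nested in PTV and the two derived targets partition the PTV
#' exactly. Both expansions are clipped to the brain outline by default
#' (standard planning practice; disable with \code{clipToBrain = FALSE}).
#'
#' @param gtv,gtvH \code{StructureMask}s with GTV_H contained in GTV.
#' @param brain Brain/body \code{StructureMask} used for clipping.
#' @param marginPTV PTV margin in mm (default 5).
#' @param marginPTVH Boost margin in mm (default 3).
#' @param clipToBrain Clip both targets to the brain mask (default TRUE).
#' @return A \code{TargetSet}. With an empty GTV_H the boost target is
#'   empty and PTV_N equals PTV.
#' @export
deriveTargets <- function(gtv, gtvH, brain, marginPTV = 5, marginPTVH = 3,
                          clipToBrain = TRUE) {
  stopIfGridMismatch(gtv, gtvH, "masks")
  if (any(gtvH@member & !gtv@member))
    stop("GTV_H must be contained in GTV")
  if (marginPTVH > marginPTV)
    stop("boost margin may not exceed the PTV margin (nesting would break)")
  clip <- if (clipToBrain) brain else NULL
  ptv <- expandMargin(gtv, marginPTV, clipTo = clip)
  ptv@name <- "PTV"
  if (any(gtvH@member)) {
    ptvH <- expandMargin(gtvH, marginPTVH, clipTo = clip)
    ## set-theoretically guaranteed, but enforce voxel-exactly
    ptvH@member <- ptvH@member & ptv@member
  } else {
    ptvH <- structureMask(gtv@grid, "PTV_H", array(FALSE, dim = gtv@grid@shape))
  }
  ptvH@name <- "PTV_H"
  ptvN <- maskDifference(ptv, ptvH, "PTV_N")
  new("TargetSet", ptv = ptv, ptvH = ptvH, ptvN = ptvN)
}
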