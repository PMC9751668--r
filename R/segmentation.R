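#' @include mask.R
NULL

#' Construct a segmentation configuration
#'
#' @param thresholdFraction Fraction of the within-GTV maximum CBF at the
#'   hypoperfused/hyperperfused junction. Default 0.25: one quarter of the
#'   maximum.
#' @param necrosisFloor Absolute CBF (ml/100g/min) below which a voxel is
#'   nonperfused. Default 1.
#' @param includeNonperfused Include nonperfused voxels in the boost
#'   subvolume GTV_H. Default \code{TRUE}.
#' @param maxPercentile \code{NA} (default) uses the raw within-GTV
#'   maximum; a value like 99 substitutes that upper percentile as a
#'   noise-robust maximum estimator.
#' @return A \code{SegmentationConfig}.
#' @export
segmentationConfig <- function(thresholdFraction = 0.25, necrosisFloor = 1,
                               includeNonperfused = TRUE,
                               maxPercentile = NA_real_) {
  new("SegmentationConfig", thresholdFraction = thresholdFraction,
      necrosisFloor = necrosisFloor, includeNonperfused = includeNonperfused,
      maxPercentile = as.numeric(maxPercentile))
}

#' Classify GTV voxels by perfusion
#'
#' Partitions the GTV into hyperperfused, hypoperfused and nonperfused
#' compartments relative to the within-GTV maximum CBF estimate M. With
#' threshold T = thresholdFraction x M, a voxel with CBF value v is
#' nonperfused if v < necrosisFloor, hypoperfused if
#' necrosisFloor <= v < T, and hyperperfused if v >= T (ties at exactly T
#' are hyperperfused: the rule is strictly below one quarter of the
#' maximum). The segmentation is scale-invariant: multiplying the CBF map
#' by any positive constant leaves the labels unchanged.
#'
#' @param cbf A \code{PerfusionMap}.
#' @param gtv The GTV \code{StructureMask}, nonempty and on the same grid.
#' @param cfg A \code{SegmentationConfig}.
#' @return A \code{PerfusionLabelMap}.
#' @examples
#' g <- imageGrid(c(4, 1, 1), c(1, 1, 1))
#' cbf <- perfusionMap(g, array(c(100, 30, 24, 0), dim = c(4, 1, 1)))
#' gtv <- structureMask(g, "GTV", array(TRUE, dim = c(4, 1, 1)))
#' classifyPerfusion(cbf, gtv, segmentationConfig())
#' @export
classifyPerfusion <- function(cbf, gtv, cfg = segmentationConfig()) {
  stopIfGridMismatch(cbf, gtv)
  inGTV <- gtv@member
  if (!any(inGTV)) stop("GTV is empty: nothing to classify")
  v <- cbf@values[inGTV]
  M <- if (is.na(cfg@maxPercentile)) max(v)
       else as.numeric(stats::quantile(v, cfg@maxPercentile / 100,
                                       type = 7, names = FALSE))
  if (M <= 0)
    stop("CBF is zero throughout the GTV: maximum is not meaningful")
  Tthr <- cfg@thresholdFraction * M
  lab <- ifelse(v < cfg@necrosisFloor, 3L, ifelse(v < Tthr, 2L, 1L))
  labels <- array(0L, dim = cbf@grid@shape)
  labels[inGTV] <- lab
  new("PerfusionLabelMap", grid = cbf@grid, labels = labels,
      maxCBF = M, threshold = Tthr)
}

#' Extract the hypoperfused boost subvolume GTV_H
#'
#' The boost subvolume is the hypoperfused compartment, plus the
#' nonperfused compartment when \code{includeNonperfused} is set (the
#' default: every voxel strictly below the threshold, perfused or not).
#'
#' @param labels A \code{PerfusionLabelMap}.
#' @param cfg A \code{SegmentationConfig}.
#' @return A \code{StructureMask} named \code{"GTV_H"}, contained in the
#'   GTV.
#' @export
extractGTVH <- function(labels, cfg = segmentationConfig()) {
  member <- labels@labels == 2L
  if (cfg@includeNonperfused) member <- member | labels@labels == 3L
  structureMask(labels@grid, "GTV_H", member)
}

#' Compartment volume report
#'
#' Volumes (cm^3) and GTV fractions of the three perfusion compartments.
#'
#' @param labels A \code{PerfusionLabelMap}.
#' @return A data.frame with columns compartment, voxels, volume_cc,
#'   fraction_of_gtv.
#' @export
compartmentReport <- function(labels) {
  vv <- prod(labels@grid@spacing) / 1000
  counts <- vapply(1:3, function(k) sum(labels@labels == k), numeric(1))
  total <- sum(counts)
  data.frame(compartment = c("hyperperfused", "hypoperfused", "nonperfused"),
             voxels = counts, volume_cc = counts * vv,
             fraction_of_gtv = counts / total)
}
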