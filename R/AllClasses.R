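#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## ImageGrid
## ---------------------------------------------------------------------------

#' Voxel lattice geometry
#'
#' An \code{ImageGrid} records the geometry shared by every volume in an
#' analysis: the number of voxels per axis, the physical voxel spacing in
#' millimetres (anisotropic grids are the norm for MR: in-plane ~1 mm,
#' slice 3 mm), and the world coordinate of the centre of the first voxel.
#' Voxel centres along axis \code{a} are at
#' \code{origin[a] + (i - 1) * spacing[a]} for 1-based index \code{i}.
#'
#' @slot shape Integer vector of length 3, voxels per axis.
#' @slot spacing Numeric vector of length 3, mm per voxel, all > 0.
#' @slot origin Numeric vector of length 3, world mm of the first voxel
#'   centre.
#'
#' @seealso [imageGrid()], [voxelVolume()]
#' @export
setClass("ImageGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@shape) != 3L || any(object@shape < 1L))
      msg <- c(msg, "'shape' must be 3 positive integers")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 positive finite reals")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "'origin' must be 3 finite reals")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Scalar volumes
## ---------------------------------------------------------------------------

#' Scalar volumes on an image grid
#'
#' \code{ScalarVolume} is the virtual parent of \code{PerfusionMap} (cerebral
#' blood flow, ml/100g/min) and \code{DoseGrid} (absorbed dose, Gy). Both
#' carry a dense 3D array of finite, nonnegative values whose dimensions
#' match the grid shape.
#'
#' @slot grid The \code{ImageGrid}.
#' @slot values 3D numeric array, finite and >= 0 everywhere.
#'
#' @aliases PerfusionMap-class DoseGrid-class
#' @export
setClass("ScalarVolume",
  representation("VIRTUAL", grid = "ImageGrid", values = "array"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
      msg <- c(msg, "array dimensions do not match grid shape")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite everywhere")
    if (any(object@values < 0))
      msg <- c(msg, "values must be nonnegative")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname ScalarVolume-class
#' @export
setClass("PerfusionMap", contains = "ScalarVolume")

#' @rdname ScalarVolume-class
#' @export
setClass("DoseGrid", contains = "ScalarVolume")

## ---------------------------------------------------------------------------
## Masks
## ---------------------------------------------------------------------------

#' Named binary structure mask
#'
#' A \code{StructureMask} is a named boolean volume on an \code{ImageGrid}:
#' GTV, PTV, an organ at risk, the brain outline. Its physical volume in
#' cm^3 is derived, never stored: see [maskVolume()].
#'
#' @slot grid The \code{ImageGrid}.
#' @slot name Structure label, e.g. \code{"GTV"}.
#' @slot member Logical 3D array matching the grid shape.
#'
#' @export
setClass("StructureMask",
  representation(grid = "ImageGrid", name = "character", member = "array"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@member))
      msg <- c(msg, "'member' must be a logical array")
    if (!identical(dim(object@member), as.integer(object@grid@shape)))
      msg <- c(msg, "mask dimensions do not match grid shape")
    if (length(object@name) != 1L || is.na(object@name))
      msg <- c(msg, "'name' must be a single string")
    if (anyNA(object@member))
      msg <- c(msg, "mask may not contain NA")
    if (is.null(msg)) TRUE else msg
  })

#' Collection of structure masks on one grid
#'
#' @slot grid The shared \code{ImageGrid}.
#' @slot masks Named list of \code{StructureMask} objects, all on that grid.
#'
#' @export
setClass("StructureSet",
  representation(grid = "ImageGrid", masks = "list"),
  validity = function(object) {
    msg <- NULL
    if (!all(vapply(object@masks, is, logical(1), "StructureMask")))
      msg <- c(msg, "all elements must be StructureMask objects")
    else if (!all(vapply(object@masks, function(m)
        identical(m@grid@shape, object@grid@shape) &&
        isTRUE(all.equal(m@grid@spacing, object@grid@spacing)), logical(1))))
      msg <- c(msg, "all masks must share the set's grid")
    if (is.null(names(object@masks)) || anyDuplicated(names(object@masks)))
      msg <- c(msg, "masks must be uniquely named")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Perfusion labels
## ---------------------------------------------------------------------------

#' Perfusion compartment labels over the GTV
#'
#' Voxel-wise classification of the gross tumor volume into hyperperfused,
#' hypoperfused and nonperfused compartments relative to the within-GTV
#' maximum CBF. Labels partition the GTV exactly; voxels outside the GTV
#' are unlabeled (0).
#'
#' @slot grid The \code{ImageGrid}.
#' @slot labels Integer 3D array: 0 outside GTV, 1 hyper, 2 hypo, 3 non.
#' @slot maxCBF The maximum-CBF estimate M used for thresholding.
#' @slot threshold The absolute threshold T = fraction x M (ml/100g/min).
#'
#' @export
setClass("PerfusionLabelMap",
  representation(grid = "ImageGrid", labels = "array",
                 maxCBF = "numeric", threshold = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@labels), as.integer(object@grid@shape)))
      msg <- c(msg, "label dimensions do not match grid shape")
    if (!all(object@labels %in% 0:3))
      msg <- c(msg, "labels must be in {0,1,2,3}")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Planning targets
## ---------------------------------------------------------------------------

#' Nested planning target volumes
#'
#' The three planning targets of a dose-painting plan: the PTV (GTV plus
#' margin), the boost target PTV_H (hypoperfused subvolume plus margin) and
#' the remainder PTV_N = PTV minus PTV_H. Validity enforces the nesting and
#' exact partition: PTV_H is contained in PTV, PTV_H and PTV_N are disjoint
#' and together cover PTV.
#'
#' @slot ptv,ptvH,ptvN \code{StructureMask}s on one grid.
#'
#' @export
setClass("TargetSet",
  representation(ptv = "StructureMask", ptvH = "StructureMask",
                 ptvN = "StructureMask"),
  validity = function(object) {
    p <- object@ptv@member; h <- object@ptvH@member; n <- object@ptvN@member
    msg <- NULL
    if (!identical(dim(p), dim(h)) || !identical(dim(p), dim(n)))
      msg <- c(msg, "targets must share one grid")
    else {
      if (any(h & !p)) msg <- c(msg, "PTV_H must be contained in PTV")
      if (any(h & n)) msg <- c(msg, "PTV_H and PTV_N must be disjoint")
      if (!identical(h | n, p)) msg <- c(msg, "PTV_H and PTV_N must partition PTV")
    }
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Specifications
## ---------------------------------------------------------------------------

#' Synthetic single-metastasis phantom specification
#'
#' All geometry in world millimetres. The tumor is an axis-aligned ellipsoid
#' layered by normalized ellipsoidal radius r in [0,1]: nonperfused core
#' (r < coreFraction), hypoperfused mantle (coreFraction <= r <
#' mantleFraction) and hyperperfused rim (r >= mantleFraction), so the
#' hypoperfused-plus-nonperfused volume fraction of the GTV equals
#' mantleFraction^3 analytically.
#'
#' @slot seed Integer seed controlling the additive CBF noise.
#' @slot grid The \code{ImageGrid} to rasterize on.
#' @slot brainCenter,brainSemiaxes Brain ellipsoid (mm).
#' @slot tumorCenter,tumorSemiaxes Tumor ellipsoid (mm).
#' @slot coreFraction,mantleFraction Radial layer boundaries, 0 <=
#'   coreFraction < mantleFraction <= 1.
#' @slot cbfRim,cbfMantle,cbfCore,cbfBackground Compartment CBF levels
#'   (ml/100g/min). The rim must exceed 4 x mantle so that in the noise-free
#'   case the mantle falls below the 25-percent-of-maximum threshold.
#' @slot noiseSD Standard deviation of additive Gaussian CBF noise,
#'   clipped at zero.
#' @slot oarLayout Named list of ellipsoid OARs, each
#'   \code{list(center=, semiaxes=)} in mm.
#'
#' @export
setClass("PhantomSpec",
  representation(seed = "integer", grid = "ImageGrid",
                 brainCenter = "numeric", brainSemiaxes = "numeric",
                 tumorCenter = "numeric", tumorSemiaxes = "numeric",
                 coreFraction = "numeric", mantleFraction = "numeric",
                 cbfRim = "numeric", cbfMantle = "numeric",
                 cbfCore = "numeric", cbfBackground = "numeric",
                 noiseSD = "numeric", oarLayout = "list"),
  validity = function(object) {
    msg <- NULL
    if (any(object@tumorSemiaxes <= 0) || any(object@brainSemiaxes <= 0))
      msg <- c(msg, "semiaxes must be positive")
    if (object@coreFraction < 0 || object@coreFraction >= 1)
      msg <- c(msg, "coreFraction must be in [0,1)")
    if (object@mantleFraction <= object@coreFraction ||
        object@mantleFraction > 1)
      msg <- c(msg, "mantleFraction must be in (coreFraction, 1]")
    if (object@cbfRim <= 4 * object@cbfMantle)
      msg <- c(msg, "cbfRim must exceed 4 * cbfMantle (mantle below 25% threshold)")
    if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Segmentation configuration
#'
#' Parameters of the CBF threshold segmentation. The boost subvolume is
#' defined by the within-GTV maximum M: voxels below
#' \code{thresholdFraction * M} are hypoperfused; voxels below
#' \code{necrosisFloor} (absolute, ml/100g/min) are nonperfused (necrotic).
#' The literal rule — strictly below one quarter of the raw maximum — is the
#' default; \code{maxPercentile} substitutes an upper percentile of the
#' within-GTV CBF for the raw maximum when a single noisy voxel should not
#' set the threshold.
#'
#' @slot thresholdFraction Fraction of M at the hypo/hyper junction
#'   (default 0.25).
#' @slot necrosisFloor Absolute CBF below which a voxel is nonperfused
#'   (default 1 ml/100g/min).
#' @slot includeNonperfused Should nonperfused voxels join the boost
#'   subvolume GTV_H? Default \code{TRUE} (strictly-below-threshold rule
#'   subsumes them).
#' @slot maxPercentile \code{NA} for the raw maximum, else a percentile in
#'   (0, 100) used as the noise-robust maximum estimator.
#'
#' @export
setClass("SegmentationConfig",
  representation(thresholdFraction = "numeric", necrosisFloor = "numeric",
                 includeNonperfused = "logical", maxPercentile = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@thresholdFraction <= 0 || object@thresholdFraction >= 1)
      msg <- c(msg, "thresholdFraction must be in (0,1)")
    if (object@necrosisFloor < 0)
      msg <- c(msg, "necrosisFloor must be >= 0")
    if (!is.na(object@maxPercentile) &&
        (object@maxPercentile <= 0 || object@maxPercentile > 100))
      msg <- c(msg, "maxPercentile must be in (0,100]")
    if (is.null(msg)) TRUE else msg
  })

#' Synthetic plan specification
#'
#' Describes one of the three plan styles: the conventional plan
#' (60 Gy to PTV, maximum-dose cap 66 Gy), the capped dose-painting plan
#' (60 Gy to PTV_N with a simultaneous integrated boost of 72 Gy to PTV_H,
#' cap 79 Gy) and the uncapped dose-painting plan (same prescriptions, no
#' cap, hotspots allowed). Dose shaping is a synthetic surrogate for an
#' inverse-optimized IMRT/SIB plan: prescription objective map, Gaussian
#' penumbra blur, wide-Gaussian background falloff, optional seeded hotspot
#' field, per-target coverage renormalization and a soft maximum-dose clamp.
#'
#' @slot planId One of \code{"plan1"}, \code{"plan2"}, \code{"plan3"}.
#' @slot prescriptions Named numeric, Gy per target structure
#'   (names among \code{"PTV"}, \code{"PTV_H"}, \code{"PTV_N"}).
#' @slot dmaxCap Global maximum-dose cap in Gy, or \code{NA} for none.
#' @slot fractionDose Dose per fraction (Gy), 2 by convention.
#' @slot penumbraSigma Gaussian penumbra sigma in mm, > 0 (0 allowed as the
#'   exact no-blur limit).
#' @slot normalizationCoverage Fraction of each target that must receive
#'   its prescription (default 0.95).
#' @slot hotspotAmplitude Peak amplitude (Gy) of the seeded hotspot
#'   perturbation inside PTV_H; 0 disables.
#' @slot bgFraction,bgSigma Background falloff: amplitude fraction of the
#'   prescription and wide-Gaussian sigma (mm) governing the low dose bath
#'   reaching distant organs at risk.
#' @slot seed Integer seed for the hotspot field.
#'
#' @seealso [planPreset()]
#' @export
setClass("PlanSpec",
  representation(planId = "character", prescriptions = "numeric",
                 dmaxCap = "numeric", fractionDose = "numeric",
                 penumbraSigma = "numeric", normalizationCoverage = "numeric",
                 hotspotAmplitude = "numeric", bgFraction = "numeric",
                 bgSigma = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@prescriptions) < 1L || any(object@prescriptions <= 0))
      msg <- c(msg, "prescriptions must be positive")
    if (is.null(names(object@prescriptions)) ||
        !all(names(object@prescriptions) %in% c("PTV", "PTV_H", "PTV_N")))
      msg <- c(msg, "prescriptions must be named PTV, PTV_H or PTV_N")
    if (!is.na(object@dmaxCap) && object@dmaxCap < max(object@prescriptions))
      msg <- c(msg, "dmaxCap must be at least the maximum prescription")
    if (object@penumbraSigma < 0)
      msg <- c(msg, "penumbraSigma must be >= 0")
    if (object@normalizationCoverage <= 0 || object@normalizationCoverage > 1)
      msg <- c(msg, "normalizationCoverage must be in (0,1]")
    if (object@hotspotAmplitude < 0)
      msg <- c(msg, "hotspotAmplitude must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Differential / cumulative dose-volume histogram
#'
#' Uniform-width dose bins; \code{diffVolume} holds the absolute structure
#' volume (cm^3) per bin and \code{cumFraction} the fraction of the
#' structure receiving at least each bin edge dose. The differential
#' volumes sum to the structure volume exactly; the cumulative curve starts
#' at 1 at 0 Gy and never increases.
#'
#' @slot structure Structure name.
#' @slot edges Bin edges in Gy (length nbins + 1, starting at 0).
#' @slot diffVolume Absolute volume (cm^3) per bin.
#' @slot cumFraction Fraction of structure volume receiving >= each edge.
#'
#' @export
setClass("DVHCurve",
  representation(structure = "character", edges = "numeric",
                 diffVolume = "numeric", cumFraction = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@edges) != length(object@diffVolume) + 1L)
      msg <- c(msg, "edges must be one longer than diffVolume")
    if (length(object@cumFraction) != length(object@edges))
      msg <- c(msg, "cumFraction must align with edges")
    if (any(diff(object@cumFraction) > 1e-12))
      msg <- c(msg, "cumulative fraction must be non-increasing")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@spacing), collapse = ", "),
              paste(format(object@origin), collapse = ", ")))
})

setMethod("show", "ScalarVolume", function(object) {
  cat(sprintf("%s on %s grid: range [%.3g, %.3g]\n", class(object),
              paste(object@grid@shape, collapse = "x"),
              min(object@values), max(object@values)))
})

setMethod("show", "StructureMask", function(object) {
  cat(sprintf("StructureMask '%s': %d voxels, %.2f cm^3\n", object@name,
              sum(object@member), maskVolume(object)))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet with %d structures on %s grid:\n",
              length(object@masks),
              paste(object@grid@shape, collapse = "x")))
  for (m in object@masks)
    cat(sprintf("  %-14s %8.2f cm^3\n", m@name, maskVolume(m)))
})

setMethod("show", "PerfusionLabelMap", function(object) {
  n <- tabulate(object@labels + 1L, nbins = 4L)
  cat(sprintf(paste0("PerfusionLabelMap: M = %.2f, T = %.2f ml/100g/min\n",
                     "  hyper %d | hypo %d | non %d voxels\n"),
              object@maxCBF, object@threshold, n[2], n[3], n[4]))
})

setMethod("show", "TargetSet", function(object) {
  cat(sprintf("TargetSet: PTV %.2f | PTV_H %.2f | PTV_N %.2f cm^3\n",
              maskVolume(object@ptv), maskVolume(object@ptvH),
              maskVolume(object@ptvN)))
})

setMethod("show", "PlanSpec", function(object) {
  rx <- paste(sprintf("%s=%g Gy", names(object@prescriptions),
                      object@prescriptions), collapse = ", ")
  cap <- if (is.na(object@dmaxCap)) "none" else sprintf("%g Gy", object@dmaxCap)
  cat(sprintf("PlanSpec '%s': %s; Dmax cap %s; coverage %.0f%%\n",
              object@planId, rx, cap, 100 * object@normalizationCoverage))
})
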