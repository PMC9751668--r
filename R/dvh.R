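#' @include dosemodel.R
NULL

maskedDoses <- function(dose, mask) {
  stopIfGridMismatch(dose, mask)
  if (!any(mask@member)) stop("structure '", mask@name, "' is empty")
  dose@values[mask@member]
}

#' Compute a dose-volume histogram
#'
#' Differential histogram of voxel doses weighted by voxel volume, on
#' uniform bins of width \code{binWidthGy} starting at 0 Gy, with the
#' cumulative curve (fraction of structure volume receiving at least each
#' bin-edge dose) derived from it. The differential volumes sum to the
#' structure volume exactly and the cumulative curve is monotonically
#' non-increasing, starting at 1 at 0 Gy.
#'
#' @param dose A \code{DoseGrid}.
#' @param mask A nonempty \code{StructureMask} on the same grid.
#' @param binWidthGy Bin width in Gy (default 0.05).
#' @return A \code{DVHCurve}.
#' @export
computeDVH <- function(dose, mask, binWidthGy = 0.05) {
  if (binWidthGy <= 0) stop("bin width must be positive")
  d <- maskedDoses(dose, mask)
  vv <- voxelVolume(mask) / 1000                 # cm^3 per voxel
  nb <- floor(max(d) / binWidthGy) + 1L
  edges <- seq(0, by = binWidthGy, length.out = nb + 1L)
  ## left-closed bins [edge, edge + width): a dose exactly at an edge counts
  ## toward "receiving >= edge", as the cumulative convention requires
  bin <- pmin(floor(d / binWidthGy) + 1L, nb)
  diffVol <- vapply(seq_len(nb), function(b) sum(bin == b), numeric(1)) * vv
  total <- length(d) * vv
  cum <- c(total, total - cumsum(diffVol)) / total
  new("DVHCurve", structure = mask@name, edges = edges,
      diffVolume = diffVol, cumFraction = pmax(cum, 0))
}

#' Dose at volume (Dp\%)
#'
#' The dose received by at least p percent of the structure volume,
#' computed by the descending-sort rank convention: with N voxel doses
#' sorted in decreasing order, Dp\% is the value at rank
#' \code{ceiling(p/100 * N)} (no interpolation). D2\% is the near-maximum
#' dose, D98\% the near-minimum, D50\% the median-volume dose.
#'
#' @param dose A \code{DoseGrid} or a bare numeric vector of voxel doses.
#' @param p Percent in (0, 100).
#' @param mask Required when \code{dose} is a \code{DoseGrid}.
#' @return Dose in Gy.
#' @examples
#' doseAtVolume(1:100, 2)   # 99
#' doseAtVolume(1:100, 98)  # 3
#' @export
doseAtVolume <- function(dose, p, mask = NULL) {
  if (p <= 0 || p >= 100) stop("p must be in (0, 100)")
  d <- if (is.numeric(dose)) dose else maskedDoses(dose, mask)
  if (length(d) == 0L) stop("empty structure: Dp% undefined")
  sort(d, decreasing = TRUE)[ceiling(p / 100 * length(d))]
}

#' Mean dose over a structure
#'
#' Volume-weighted arithmetic mean of voxel doses (all voxels share one
#' volume, so this is the plain mean). Note the distinction from D50\%,
#' the median-volume dose, which is reported alongside in [planMetrics()].
#'
#' @param dose A \code{DoseGrid}.
#' @param mask A nonempty \code{StructureMask}.
#' @return Mean dose in Gy.
#' @export
meanDose <- function(dose, mask) mean(maskedDoses(dose, mask))

#' Target coverage
#'
#' Percent of the structure volume receiving at least
#' \code{levelFraction x rxGy}.
#'
#' @param dose A \code{DoseGrid}.
#' @param mask A nonempty \code{StructureMask}.
#' @param rxGy Prescription dose, Gy (> 0).
#' @param levelFraction Fraction of the prescription defining the coverage
#'   level (default 1).
#' @return Coverage in percent, 0..100.
#' @export
targetCoverage <- function(dose, mask, rxGy, levelFraction = 1) {
  if (rxGy <= 0) stop("prescription must be positive")
  d <- maskedDoses(dose, mask)
  100 * sum(d >= levelFraction * rxGy) / length(d)
}

#' Paddick conformity index
#'
#' CI = (V_t,ref / V_t) x (V_t,ref / V_ref), where V_t is the target
#' volume, V_t,ref the target volume covered by the prescription isodose
#' and V_ref the total volume covered by the prescription isodose within
#' the evaluation region. CI lies in [0, 1]; 1 means the prescription
#' isodose coincides with the target; 0 when the isodose misses the target
#' entirely (or is empty). The evaluation region defaults to the whole
#' grid; pass the brain/body mask so background air cannot inflate
#' conformity.
#'
#' @param dose A \code{DoseGrid}.
#' @param target A nonempty \code{StructureMask}.
#' @param rxGy Prescription dose, Gy.
#' @param evalRegion Optional \code{StructureMask} restricting V_ref.
#' @return CI in [0, 1].
#' @export
conformityIndex <- function(dose, target, rxGy, evalRegion = NULL) {
  if (rxGy <= 0) stop("prescription must be positive")
  stopIfGridMismatch(dose, target)
  iso <- dose@values >= rxGy
  if (!is.null(evalRegion)) {
    stopIfGridMismatch(dose, evalRegion)
    iso <- iso & evalRegion@member
  }
  vt <- sum(target@member)
  if (vt == 0L) stop("empty target")
  vref <- sum(iso)
  vtref <- sum(iso & target@member)
  if (vref == 0L) return(0)
  (vtref / vt) * (vtref / vref)
}

#' Index of achievement (IOA)
#'
#' One plus the volume-weighted mean squared relative deviation of planned
#' dose from prescription, accumulated over the assigned targets:
#' \deqn{IOA = 1 + \sum_K \sum_j \left(\frac{D_j - D_{K,RX}}{D_{K,RX}}\right)^2
#'   \frac{dDVH_{PTV(K)}(D_j)}{V_{PTV(K)}}}
#' with \eqn{D_j} the differential-DVH bin centres. IOA is always >= 1 and
#' equals 1 (up to binning tolerance) iff the dose equals the prescription
#' throughout every assigned target. The per-structure IOA reported in
#' plan tables is the single-target case.
#'
#' @param dose A \code{DoseGrid}.
#' @param assignment List of \code{list(mask =, rx =)} pairs: each target
#'   with its prescription in Gy.
#' @param binWidthGy Differential-DVH bin width (default 0.05 Gy). Use
#'   \code{binWidthGy = 0} for the exact voxel-wise (unbinned) evaluation.
#' @return IOA >= 1.
#' @export
indexOfAchievement <- function(dose, assignment, binWidthGy = 0.05) {
  if (!length(assignment)) stop("empty prescription assignment")
  dev <- 0
  for (a in assignment) {
    if (is.null(a$rx) || a$rx <= 0) stop("prescriptions must be positive")
    d <- maskedDoses(dose, a$mask)
    if (binWidthGy > 0) {
      dvh <- computeDVH(dose, a$mask, binWidthGy)
      centers <- dvh@edges[-length(dvh@edges)] + binWidthGy / 2
      vt <- sum(dvh@diffVolume)
      dev <- dev + sum(((centers - a$rx) / a$rx)^2 * dvh@diffVolume) / vt
    } else {
      dev <- dev + mean(((d - a$rx) / a$rx)^2)
    }
  }
  1 + dev
}

#' Per-structure plan metrics
#'
#' Evaluates one simulated dose grid against the plan's prescriptions:
#' for each target D2\%, D98\%, D50\%, Dmean (arithmetic), coverage at the
#' prescription, CI and IOA; for each organ at risk, Dmax. Prescriptions
#' follow the plan style: the conventional plan evaluates every target at
#' 60 Gy; the dose-painting plans evaluate PTV_H at the boost dose and
#' PTV/PTV_N at the base dose.
#'
#' @param dose A \code{DoseGrid}.
#' @param targets A \code{TargetSet}.
#' @param brain Brain \code{StructureMask}, the CI evaluation region.
#' @param plan The \code{PlanSpec} that produced the dose.
#' @param oars Optional list / \code{StructureSet} of OAR masks.
#' @param binWidthGy IOA bin width (default 0.05).
#' @return A long-format data.frame with columns structure, metric, value.
#' @export
planMetrics <- function(dose, targets, brain, plan, oars = NULL,
                        binWidthGy = 0.05) {
  rx <- plan@prescriptions
  base <- if ("PTV" %in% names(rx)) rx[["PTV"]] else rx[["PTV_N"]]
  rxFor <- function(nm) {
    if (nm == "PTV_H" && "PTV_H" %in% names(rx)) rx[["PTV_H"]] else base
  }
  tlist <- list(PTV = targets@ptv, PTV_H = targets@ptvH, PTV_N = targets@ptvN)
  rows <- list()
  for (nm in names(tlist)) {
    m <- tlist[[nm]]
    if (!any(m@member)) next
    r <- rxFor(nm)
    d <- maskedDoses(dose, m)
    n <- length(d)
    vals <- c(
      D2 = doseAtVolume(d, 2), D98 = doseAtVolume(d, 98),
      D50 = doseAtVolume(d, 50), Dmean = mean(d),
      coverage = 100 * sum(d >= r) / n,
      CI = conformityIndex(dose, m, r, evalRegion = brain),
      IOA = indexOfAchievement(dose, list(list(mask = m, rx = r)),
                               binWidthGy),
      volume_cc = maskVolume(m))
    rows[[nm]] <- data.frame(structure = nm, metric = names(vals),
                             value = unname(vals))
  }
  if (!is.null(oars)) {
    rep <- oarDmaxReport(dose, oars)
    rep <- rep[!is.na(rep$dmax_gy), ]
    if (nrow(rep))
      rows[["oars"]] <- data.frame(structure = rep$name, metric = "Dmax",
                                   value = rep$dmax_gy)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}
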