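#' @include blur.R geometry.R
NULL

#' Plan presets
#'
#' The three plan styles compared by the pipeline, all at 2 Gy per
#' fraction:
#' \describe{
#'   \item{plan1}{Conventional: 60 Gy prescribed to the whole PTV, global
#'     maximum-dose cap 66 Gy (110\% of prescription).}
#'   \item{plan2}{Capped dose painting: 60 Gy to PTV_N with a simultaneous
#'     integrated boost of 72 Gy to PTV_H, cap 79 Gy (110\% of the boost
#'     prescription).}
#'   \item{plan3}{Uncapped dose painting: as plan2 but with no cap and a
#'     seeded hotspot perturbation inside PTV_H surviving (hotspot
#'     amplitude 6 Gy by default).}
#' }
#'
#' @param planId \code{"plan1"}, \code{"plan2"} or \code{"plan3"}.
#' @param penumbraSigma Gaussian penumbra sigma, mm (default 3).
#' @param normalizationCoverage Coverage fraction each target must receive
#'   at its prescription (default 0.95).
#' @param hotspotAmplitude Hotspot amplitude in Gy; default 0 for
#'   plan1/plan2, 6 for plan3.
#' @param bgFraction,bgSigma Background-falloff amplitude fraction and
#'   sigma (mm); defaults 0.30 and 40.
#' @param seed Integer seed for the hotspot field.
#' @return A \code{PlanSpec}.
#' @export
planPreset <- function(planId = c("plan1", "plan2", "plan3"),
                       penumbraSigma = 3, normalizationCoverage = 0.95,
                       hotspotAmplitude = NULL, bgFraction = 0.30,
                       bgSigma = 40, seed = 1L) {
  planId <- match.arg(planId)
  rx <- switch(planId,
    plan1 = c(PTV = 60),
    plan2 = c(PTV_N = 60, PTV_H = 72),
    plan3 = c(PTV_N = 60, PTV_H = 72))
  cap <- switch(planId, plan1 = 66, plan2 = 79, plan3 = NA_real_)
  if (is.null(hotspotAmplitude))
    hotspotAmplitude <- if (planId == "plan3") 6 else 0
  new("PlanSpec", planId = planId, prescriptions = rx, dmaxCap = cap,
      fractionDose = 2, penumbraSigma = penumbraSigma,
      normalizationCoverage = normalizationCoverage,
      hotspotAmplitude = hotspotAmplitude, bgFraction = bgFraction,
      bgSigma = bgSigma, seed = as.integer(seed))
}

#' Default organ-at-risk dose constraints
#'
#' Maximum-dose limits in Gy: eye 50, optic nerve 54, lens 8,
#' brainstem 54.
#'
#' @return A data.frame with columns \code{name} and \code{dmax_limit_gy}
#'   matching the canonical OAR atlas names.
#' @export
oarConstraints <- function() {
  data.frame(
    name = c("Eye-L", "Eye-R", "OpticNerve-L", "OpticNerve-R",
             "Lens-L", "Lens-R", "Brainstem"),
    dmax_limit_gy = c(50, 50, 54, 54, 8, 8, 54))
}

#' Simulate a plan's dose distribution
#'
#' A seeded synthetic surrogate for an inverse-optimized IMRT/SIB plan; it
#' reproduces the prescription structure, penumbra falloff, coverage
#' normalization and maximum-dose cap of each plan style without modelling
#' beams or fluence. Pipeline: (1) objective map — each voxel receives its
#' enclosing target's prescription, the boost target taking precedence;
#' (2) Gaussian penumbra blur (physical mm, anisotropy-aware); (3) a wide
#' Gaussian background bath so distant organs at risk receive
#' distance-dependent low doses; (4) optional seeded hotspot field inside
#' PTV_H; (5) per-target renormalization so the configured coverage
#' fraction of every target receives at least its prescription — a global
#' scale for the base target and a smooth local scale for the boost
#' target; (6) with a cap set, a soft-knee clamp keeps the global maximum
#' at or below the cap, and normalization is re-checked (at most 10
#' rounds). Deterministic given the plan seed.
#'
#' @param targets A \code{TargetSet}.
#' @param brain Brain \code{StructureMask} (evaluation region).
#' @param plan A \code{PlanSpec}.
#' @return A \code{DoseGrid}.
#' @export
simulatePlanDose <- function(targets, brain, plan) {
  validObject(plan)
  grid <- targets@ptv@grid
  sp <- grid@spacing
  rx <- plan@prescriptions

  masks <- list(PTV = targets@ptv@member, PTV_H = targets@ptvH@member,
                PTV_N = targets@ptvN@member)
  tmasks <- list(PTV = targets@ptv, PTV_H = targets@ptvH, PTV_N = targets@ptvN)
  rxBase <- min(rx)

  ## Objective map on targets dilated by ~2 sigma, so that after the
  ## penumbra blur the prescription plateau still covers the target (the
  ## role the fluence optimizer plays in a real plan). The boost target is
  ## painted last and wins; its dilated rim bleeding into PTV_N mimics the
  ## unavoidable dose gradient around a simultaneous integrated boost.
  dil <- 2 * plan@penumbraSigma
  obj <- array(0, dim = grid@shape)
  objBase <- array(0, dim = grid@shape)
  for (nm in names(sort(rx))) {
    m <- tmasks[[nm]]
    if (!any(m@member)) next
    md <- if (dil > 0) suppressWarnings(expandMargin(m, dil))@member else m@member
    obj[md] <- rx[[nm]]
    objBase[md] <- rxBase
  }

  dose <- gaussianBlur(obj, plan@penumbraSigma, sp)
  ## Low-dose bath: a wide-Gaussian surround normalized against the
  ## base-prescription field, so distant organs at risk see
  ## distance-dependent dose that grows only a few percent when just the
  ## boost subvolume is escalated. Applied after coverage normalization
  ## (its level, <= bgFraction x base prescription, cannot influence
  ## target coverage or caps).
  bath <- if (plan@bgFraction > 0) {
    b <- gaussianBlur(obj, plan@bgSigma, sp)
    ref <- if (identical(obj, objBase)) b
           else gaussianBlur(objBase, plan@bgSigma, sp)
    plan@bgFraction * rxBase * b / max(ref)
  } else NULL

  if (plan@hotspotAmplitude > 0 && any(masks$PTV_H)) {
    noise <- withLocalSeed(plan@seed,
      array(stats::rnorm(prod(grid@shape)), dim = grid@shape))
    field <- gaussianBlur(noise - min(noise), 4, sp)
    field <- field - mean(field)
    pk <- max(field[masks$PTV_H])
    if (pk > 0) {
      bump <- pmax(field, 0) / pk * plan@hotspotAmplitude
      dose[masks$PTV_H] <- dose[masks$PTV_H] + bump[masks$PTV_H]
    }
  }

  ## smooth local weight for boost renormalization
  boostW <- if (any(masks$PTV_H) && "PTV_H" %in% names(rx)) {
    w <- gaussianBlur(masks$PTV_H + 0, max(plan@penumbraSigma, 1), sp)
    w / max(w)
  } else NULL

  covP <- 100 * plan@normalizationCoverage
  targetsOrdered <- names(sort(rx))        # base prescription first
  for (iter in seq_len(10L)) {
    for (nm in targetsOrdered) {
      mm <- masks[[nm]]
      if (!any(mm)) next
      d <- dose[mm]
      dcov <- doseAtVolume(d, covP)
      if (dcov <= 0) stop("degenerate dose: coverage dose is zero for ", nm)
      s <- rx[[nm]] / dcov
      if (s <= 1 + 1e-12) next   # coverage goal already met; never scale down
      s <- s * (1 + 1e-9)        # nudge past floating-point ties at the rank voxel
      if (nm == "PTV_H" && !is.null(boostW)) {
        ## aim the local scale at the voxel that sets the coverage dose:
        ## its (sub-unit) weight would otherwise slow convergence
        rank <- ceiling(covP / 100 * length(d))
        critical <- which(mm)[order(d, decreasing = TRUE)[rank]]
        wc <- max(boostW[critical], 0.05)
        dose <- dose * (1 + (s - 1) / wc * boostW)
      } else {
        dose <- dose * s
      }
    }
    if (!is.na(plan@dmaxCap)) dose <- softCap(dose, max(rx), plan@dmaxCap)
    ok <- vapply(targetsOrdered, function(nm) {
      mm <- masks[[nm]]
      !any(mm) || doseAtVolume(dose[mm], covP) >= rx[[nm]] - 1e-9
    }, logical(1))
    if (all(ok)) break
    if (iter == 10L)
      stop("plan '", plan@planId, "': maximum-dose cap ", plan@dmaxCap,
           " Gy conflicts with the ", covP,
           "% coverage goal; cannot satisfy both")
  }
  if (!is.null(bath)) {
    if (!is.na(plan@dmaxCap)) bath <- pmin(bath, plan@dmaxCap)
    dose <- pmax(dose, bath)
  }
  doseGrid(grid, pmax(dose, 0))
}

## Soft-knee compression: values above the knee are exponentially
## compressed toward the cap, which is approached but never exceeded;
## values at or below the knee are untouched, so coverage normalized at a
## prescription <= knee survives the clamp.
softCap <- function(dose, knee, cap) {
  if (cap <= knee) return(pmin(dose, cap))
  w <- cap - knee
  over <- dose > knee
  dose[over] <- knee + w * (1 - exp(-(dose[over] - knee) / w))
  dose
}

#' Organ-at-risk maximum-dose report
#'
#' Maximum dose over each OAR mask against its limit. An empty OAR mask
#' has no defined maximum and is reported as missing (\code{NA}), never as
#' zero.
#'
#' @param dose A \code{DoseGrid}.
#' @param oars List of \code{StructureMask}s (or a \code{StructureSet}).
#' @param constraints A data.frame like [oarConstraints()].
#' @return A data.frame with columns name, dmax_gy, limit_gy, pass.
#' @export
oarDmaxReport <- function(dose, oars, constraints = oarConstraints()) {
  if (is(oars, "StructureSet")) oars <- oars@masks
  rows <- lapply(oars, function(m) {
    stopIfGridMismatch(dose, m)
    dm <- if (any(m@member)) max(dose@values[m@member]) else NA_real_
    lim <- constraints$dmax_limit_gy[match(m@name, constraints$name)]
    data.frame(name = m@name, dmax_gy = dm, limit_gy = lim,
               pass = if (is.na(dm) || is.na(lim)) NA else dm < lim)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
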