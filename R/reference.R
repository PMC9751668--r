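#' @include cohort.R
NULL

#' Reference cohort summary tables
#'
#' Mean (and SD) summary tables from a published 50-patient clinical
#' cohort of single brain metastases treated with perfusion-guided dose
#' painting, shipped as plain-text reference inputs. They serve two
#' purposes: the derived quantities printed alongside them (volume ratios,
#' between-plan increment percentages) are exactly recomputable from these
#' means with [incrementPercent()], and the phantom generator's default
#' study conditions (GTV volume range 8.4-118 cm^3, hypoperfused fraction
#' 49.3\%) are anchored to them.
#'
#' @param which One of \code{"volumes"} (structure volumes in cm^3 with
#'   volume-ratio percentages), \code{"targets"} (per-plan means of
#'   coverage, CI, IOA, D2\%, D98\%, Dmean for PTV, PTV_H, PTV_N) or
#'   \code{"oars"} (per-plan mean Dmax per organ at risk).
#' @return A data.frame.
#' @examples
#' v <- referenceCohort("volumes")
#' 100 * v$mean_cc[v$structure == "GTV_H"] / v$mean_cc[v$structure == "GTV"]
#' @export
referenceCohort <- function(which = c("volumes", "targets", "oars")) {
  which <- match.arg(which)
  f <- switch(which,
    volumes = "reference_volumes.csv",
    targets = "reference_target_metrics.csv",
    oars = "reference_oar_dmax.csv")
  utils::read.csv(system.file("extdata", f, package = "perfpaint",
                              mustWork = TRUE))
}
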