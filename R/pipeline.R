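#' @include reference.R io.R phantom.R segmentation.R
NULL

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end simulation: cohort size and seed,
#' grid, phantom volume range, segmentation configuration, target margins,
#' the three plan styles and the metric options. The defaults are the
#' study conditions: GTV volumes log-uniform in 8.4-118 cm^3, a 25\%
#' threshold segmentation, 5/3 mm margins, and plans at 60/72 Gy with
#' caps 66/79/none.
#'
#' @param seed Master seed; every random draw in the run derives from it.
#' @param nSubjects Number of phantoms (default 3).
#' @param grid Shared \code{ImageGrid}.
#' @param volumeRange GTV volume range, cm^3.
#' @param segmentation A \code{SegmentationConfig}.
#' @param marginPTV,marginPTVH Margins in mm (defaults 5 and 3).
#' @param planIds Plan styles to simulate.
#' @param penumbraSigma Penumbra sigma (mm) shared by the plans.
#' @param binWidthGy DVH/IOA bin width (default 0.05).
#' @param outdir Optional output directory; when given, metric and
#'   summary CSVs plus a JSON manifest are written.
#' @param writeVolumes Also write each subject's CBF map, masks and dose
#'   grids as NIfTI under \code{outdir} (slow; default FALSE).
#' @return A named list with class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1L, nSubjects = 3L, grid = defaultGrid(),
                           volumeRange = c(8.4, 118),
                           segmentation = segmentationConfig(),
                           marginPTV = 5, marginPTVH = 3,
                           planIds = c("plan1", "plan2", "plan3"),
                           penumbraSigma = 3, binWidthGy = 0.05,
                           outdir = NULL, writeVolumes = FALSE) {
  structure(list(seed = as.integer(seed), nSubjects = as.integer(nSubjects),
                 grid = grid, volumeRange = volumeRange,
                 segmentation = segmentation, marginPTV = marginPTV,
                 marginPTVH = marginPTVH, planIds = planIds,
                 penumbraSigma = penumbraSigma, binWidthGy = binWidthGy,
                 outdir = outdir, writeVolumes = writeVolumes),
            class = "pipelineConfig")
}

## Polynomial rolling hash of the serialized config, recorded in the
## manifest so a rerun can be matched to its configuration.
configHash <- function(config) {
  s <- utils::capture.output(utils::str(config, digits.d = 12))
  bytes <- utf8ToInt(paste(s, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full dose-painting simulation pipeline
#'
#' For each subject: generate a phantom (CBF map, brain, GTV, OARs),
#' segment the hypoperfused boost subvolume GTV_H, derive the nested
#' planning targets, simulate each plan's dose grid, and evaluate the
#' dosimetric indices; then aggregate the cohort summary (means, SDs,
#' increment percentages, ANOVA with LSD). A rerun with the same
#' configuration reproduces every number exactly.
#'
#' @param config A [pipelineConfig()].
#' @return List with elements \code{metrics} (long-format per-subject
#'   table), \code{summary} (cohort summary data.frame), \code{subjects}
#'   (per-subject volumes and segmentation fractions) and
#'   \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  specs <- sampleCohort(config$nSubjects, config$seed,
                        volumeRange = config$volumeRange,
                        grid = config$grid)
  allMetrics <- list()
  subjRows <- list()
  oarNames <- names(defaultOARLayout(c(0, 0, 0), c(1, 1, 1)))
  for (i in seq_along(specs)) {
    sid <- sprintf("subj%02d", i)
    stage <- "phantom"
    res <- tryCatch({
      ph <- generatePhantom(specs[[i]])
      stage <- "segmentation"
      labels <- classifyPerfusion(ph$cbf, ph$structures[["GTV"]],
                                  config$segmentation)
      gtvH <- extractGTVH(labels, config$segmentation)
      stage <- "geometry"
      targets <- deriveTargets(ph$structures[["GTV"]], gtvH,
                               ph$structures[["brain"]],
                               config$marginPTV, config$marginPTVH)
      stage <- "dose"
      oars <- ph$structures@masks[intersect(oarNames,
                                            structureNames(ph$structures))]
      rows <- list()
      doses <- list()
      for (p in seq_along(config$planIds)) {
        plan <- planPreset(config$planIds[p],
                           penumbraSigma = config$penumbraSigma,
                           seed = config$seed * 1000L + i * 10L + p)
        dose <- simulatePlanDose(targets, ph$structures[["brain"]], plan)
        doses[[plan@planId]] <- dose
        stage <- "metrics"
        pm <- planMetrics(dose, targets, ph$structures[["brain"]], plan,
                          oars = oars, binWidthGy = config$binWidthGy)
        pm$subject <- sid
        pm$plan <- plan@planId
        rows[[plan@planId]] <- pm
      }
      list(ph = ph, gtvH = gtvH, targets = targets, doses = doses,
           metrics = do.call(rbind, c(rows, make.row.names = FALSE)))
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed for subject ", sid, ": ",
           conditionMessage(e))
    })
    allMetrics[[sid]] <- res$metrics
    gtvV <- maskVolume(res$ph$structures[["GTV"]])
    subjRows[[sid]] <- data.frame(
      subject = sid,
      gtv_cc = gtvV,
      gtv_h_cc = maskVolume(res$gtvH),
      hypo_fraction = maskVolume(res$gtvH) / gtvV,
      ptv_cc = maskVolume(res$targets@ptv),
      ptv_h_cc = maskVolume(res$targets@ptvH),
      ptv_n_cc = maskVolume(res$targets@ptvN))
    if (!is.null(config$outdir) && config$writeVolumes) {
      sdir <- file.path(config$outdir, sid)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      writeVolume(res$ph$cbf, file.path(sdir, "cbf.nii.gz"))
      for (nm in structureNames(res$ph$structures))
        writeVolume(res$ph$structures[[nm]],
                    file.path(sdir, paste0(gsub("[^A-Za-z0-9]", "_", nm), ".nii.gz")))
      writeVolume(res$gtvH, file.path(sdir, "GTV_H.nii.gz"))
      writeVolume(res$targets@ptv, file.path(sdir, "PTV.nii.gz"))
      writeVolume(res$targets@ptvH, file.path(sdir, "PTV_H.nii.gz"))
      writeVolume(res$targets@ptvN, file.path(sdir, "PTV_N.nii.gz"))
      for (pid in names(res$doses))
        writeVolume(res$doses[[pid]], file.path(sdir, paste0("dose_", pid, ".nii.gz")))
    }
  }
  metrics <- do.call(rbind, c(unname(allMetrics), make.row.names = FALSE))
  metrics <- metrics[c("subject", "plan", "structure", "metric", "value")]
  subjects <- do.call(rbind, c(unname(subjRows), make.row.names = FALSE))
  summary <- summarizeCohort(metrics)
  manifest <- list(
    package = "perfpaint",
    version = as.character(utils::packageVersion("perfpaint")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_subjects = config$nSubjects,
    config_hash = configHash(config),
    grid = list(shape = config$grid@shape, spacing = config$grid@spacing))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(config$outdir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(subjects, file.path(config$outdir, "subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config$outdir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(metrics = metrics, summary = summary, subjects = subjects,
       manifest = manifest)
}
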