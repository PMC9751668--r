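#' @include mask.R
NULL

#' Canonical organ-at-risk layout
#'
#' A fixed atlas of ellipsoidal organs at risk placed relative to the brain
#' ellipsoid: two eyes (anterior, outside the brain outline) with embedded
#' lenses, two optic nerves approximated by elongated ellipsoids bridging
#' eye and brain, and one brainstem (inferior, midline). Organ sizes are
#' anatomically plausible absolute millimetres; positions scale with the
#' brain semiaxes so the atlas adapts to any grid. Only maximum-dose
#' sampling is required of these structures, not anatomical fidelity.
#'
#' @param brainCenter,brainSemiaxes Brain ellipsoid, world mm.
#' @return Named list of \code{list(center=, semiaxes=)} entries:
#'   Eye-L, Eye-R, Lens-L, Lens-R, OpticNerve-L, OpticNerve-R, Brainstem.
#' @export
defaultOARLayout <- function(brainCenter, brainSemiaxes) {
  b <- brainSemiaxes
  eyeY <- brainCenter[2] - (b[2] + 14)
  eyeZ <- brainCenter[3] - 0.30 * b[3]
  eyeX <- 0.35 * b[1]
  eye <- function(s) list(center = c(brainCenter[1] + s * eyeX, eyeY, eyeZ),
                          semiaxes = c(11, 11, 11))
  lens <- function(s) list(center = c(brainCenter[1] + s * eyeX, eyeY - 8, eyeZ),
                           semiaxes = c(4, 2, 4))
  nerve <- function(s) list(center = c(brainCenter[1] + s * (eyeX - 4),
                                       eyeY + 18, eyeZ + 2),
                            semiaxes = c(2.5, 12, 2.5))
  list(
    "Eye-L" = eye(-1), "Eye-R" = eye(1),
    "Lens-L" = lens(-1), "Lens-R" = lens(1),
    "OpticNerve-L" = nerve(-1), "OpticNerve-R" = nerve(1),
    "Brainstem" = list(center = c(brainCenter[1],
                                  brainCenter[2] + 0.05 * b[2],
                                  brainCenter[3] - 0.70 * b[3]),
                       semiaxes = c(9, 11, pmin(24, 0.35 * b[3] * 3)))
  )
}

#' Construct a phantom specification
#'
#' Defaults emulate a mid-sized single brain metastasis: a 20 x 15 x 10 mm
#' semiaxis tumor (12.6 cm^3) offset posterior-superior within the brain,
#' with a hyperperfused rim, a hypoperfused mantle and a small necrotic
#' core. The default mantle fraction 0.493^(1/3) makes the
#' hypoperfused-plus-nonperfused compartment occupy 49.3% of the GTV by
#' volume analytically. Compartment CBF magnitudes are configurable
#' stand-ins (no per-compartment reference values exist for metastases);
#' defaults: rim 100, mantle 15, core 0.3, brain background 40
#' ml/100g/min, noise SD 2.
#'
#' @param seed Integer seed for the CBF noise.
#' @param grid \code{ImageGrid}; default [defaultGrid()].
#' @param brainSemiaxes Brain ellipsoid semiaxes (mm); default 62% of the
#'   grid half-extent per axis, leaving room for the anterior eyes.
#' @param tumorCenter Tumor centre (mm); default offset from the brain
#'   centre by 25%, 10% and 25% of the brain semiaxes.
#' @param tumorSemiaxes Tumor ellipsoid semiaxes (mm).
#' @param hypoFraction Target hypoperfused-plus-nonperfused volume fraction
#'   of the GTV; sets \code{mantleFraction = hypoFraction^(1/3)}.
#' @param coreFraction Radial fraction of the nonperfused core; default
#'   35% of the mantle fraction (core volume ~4% of GTV).
#' @param cbfRim,cbfMantle,cbfCore,cbfBackground Compartment CBF levels.
#' @param noiseSD Additive Gaussian CBF noise SD (clipped at 0).
#' @param oarLayout OAR atlas; default [defaultOARLayout()].
#' @return A \code{PhantomSpec}.
#' @export
phantomSpec <- function(seed = 1L, grid = defaultGrid(),
                        brainSemiaxes = 0.62 * gridExtent(grid) / 2,
                        tumorCenter = NULL,
                        tumorSemiaxes = c(20, 15, 10),
                        hypoFraction = 0.493,
                        coreFraction = 0.35 * hypoFraction^(1 / 3),
                        cbfRim = 100, cbfMantle = 15, cbfCore = 0.3,
                        cbfBackground = 40, noiseSD = 2,
                        oarLayout = NULL) {
  bc <- gridCenter(grid)
  if (is.null(tumorCenter))
    tumorCenter <- bc + c(0.25, 0.10, 0.25) * brainSemiaxes
  if (is.null(oarLayout))
    oarLayout <- defaultOARLayout(bc, brainSemiaxes)
  new("PhantomSpec", seed = as.integer(seed), grid = grid,
      brainCenter = bc, brainSemiaxes = as.numeric(brainSemiaxes),
      tumorCenter = as.numeric(tumorCenter),
      tumorSemiaxes = as.numeric(tumorSemiaxes),
      coreFraction = coreFraction,
      mantleFraction = hypoFraction^(1 / 3),
      cbfRim = cbfRim, cbfMantle = cbfMantle, cbfCore = cbfCore,
      cbfBackground = cbfBackground, noiseSD = noiseSD,
      oarLayout = oarLayout)
}

#' Analytic tumor volume of a phantom spec
#'
#' Closed-form ellipsoid volume 4/3 pi a b c, in cm^3.
#'
#' @param spec A \code{PhantomSpec}.
#' @return Volume in cm^3.
#' @export
analyticTumorVolume <- function(spec)
  4 / 3 * pi * prod(spec@tumorSemiaxes) / 1000

#' Generate a synthetic single-metastasis phantom
#'
#' Rasterizes the brain and tumor ellipsoids and the OAR atlas on the
#' spec's grid and builds a CBF map: brain background outside the tumor,
#' and inside the GTV a rim/mantle/core layering by normalized ellipsoidal
#' radius, plus seeded additive Gaussian noise clipped at zero (CBF cannot
#' be negative). Identical specs (including seed) give bit-identical
#' output.
#'
#' @param spec A \code{PhantomSpec}.
#' @return List with elements \code{cbf} (a \code{PerfusionMap}) and
#'   \code{structures} (a \code{StructureSet} holding \code{brain},
#'   \code{GTV} and the OARs).
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7, grid = imageGrid(c(64, 64, 24))))
#' maskVolume(ph$structures[["GTV"]])
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  grid <- spec@grid
  lo <- spec@tumorCenter - spec@tumorSemiaxes
  hi <- spec@tumorCenter + spec@tumorSemiaxes
  gmin <- grid@origin
  gmax <- grid@origin + gridExtent(grid)
  if (any(lo < gmin) || any(hi > gmax))
    stop("geometry error: tumor ellipsoid extends outside the grid")

  brain <- ellipsoidMask(grid, spec@brainCenter, spec@brainSemiaxes, "brain")
  r2 <- ellipsoidRadius2(grid, spec@tumorCenter, spec@tumorSemiaxes)
  gtvArr <- r2 <= 1
  if (any(gtvArr & !brain@member))
    stop("geometry error: tumor ellipsoid extends outside the brain")
  gtv <- structureMask(grid, "GTV", gtvArr)

  cbf <- array(0, dim = grid@shape)
  cbf[brain@member] <- spec@cbfBackground
  r <- sqrt(r2[gtvArr])
  layer <- ifelse(r < spec@coreFraction, spec@cbfCore,
                  ifelse(r < spec@mantleFraction, spec@cbfMantle,
                         spec@cbfRim))
  cbf[gtvArr] <- layer
  if (spec@noiseSD > 0) {
    noise <- withLocalSeed(spec@seed,
      array(stats::rnorm(length(cbf), 0, spec@noiseSD), dim = grid@shape))
    cbf <- cbf + noise
  }
  cbf <- pmax(cbf, 0)

  masks <- list(brain = brain, GTV = gtv)
  for (nm in names(spec@oarLayout)) {
    o <- spec@oarLayout[[nm]]
    masks[[nm]] <- ellipsoidMask(grid, o$center, o$semiaxes, nm)
  }
  list(cbf = perfusionMap(grid, cbf),
       structures = structureSet(grid, masks))
}

#' Sample a cohort of phantom specifications
#'
#' Tumor volumes are drawn log-uniformly within \code{volumeRange} — the
#' right-skewed draw reflecting that cohort mean volumes sit well below the
#' midpoint of the observed range — with mildly anisotropic axis ratios,
#' jittered tumor centres kept inside the brain, and per-subject
#' hypoperfused fractions drawn around \code{hypoFractionMean} (truncated
#' normal, SD 0.06, bounds 0.25 to 0.75). Sampling is fully seeded and
#' reproducible; each spec receives its own derived noise seed.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed for the sampler.
#' @param volumeRange Length-2 positive increasing vector, cm^3; default
#'   c(8.4, 118), the observed single-metastasis GTV range.
#' @param grid \code{ImageGrid} shared by the cohort.
#' @param hypoFractionMean Mean hypoperfused fraction of GTV (default
#'   0.493).
#' @param ... Further arguments passed to [phantomSpec()] (e.g. CBF
#'   levels, noiseSD).
#' @return List of \code{n} \code{PhantomSpec} objects.
#' @export
sampleCohort <- function(n, seed, volumeRange = c(8.4, 118),
                         grid = defaultGrid(), hypoFractionMean = 0.493,
                         ...) {
  if (n < 1) stop("n must be >= 1")
  if (length(volumeRange) != 2L || volumeRange[1] <= 0 ||
      volumeRange[2] <= volumeRange[1])
    stop("volumeRange must be an increasing positive pair")
  bs <- 0.62 * gridExtent(grid) / 2
  bc <- gridCenter(grid)
  dirs <- fibonacciSphere(128)
  withLocalSeed(seed, {
    lapply(seq_len(n), function(i) {
      v <- exp(stats::runif(1, log(volumeRange[1]), log(volumeRange[2])))
      u <- stats::runif(3, 0.75, 1.30)
      s <- (3 * v * 1000 / (4 * pi))^(1 / 3)   # mm, equivalent-sphere radius
      semi <- s * u / prod(u)^(1 / 3)
      ## pull the axis ratios toward isotropy until the tumor fits the brain
      while (any(semi > 0.92 * bs)) {
        u <- sqrt(u)
        semi <- s * u / prod(u)^(1 / 3)
      }
      hf <- min(0.75, max(0.25, stats::rnorm(1, hypoFractionMean, 0.06)))
      room <- pmax(bs - semi, 0)
      base <- c(0.18, 0.08, 0.15) * bs
      off <- pmin(base, 0.4 * room) + stats::runif(3, -1, 1) * 0.2 * room
      ## shrink the offset until the whole tumor surface sits inside the brain
      while (surfaceMaxRadius2(off, semi, bs, dirs) > 0.97) off <- 0.8 * off
      phantomSpec(seed = sample.int(.Machine$integer.max, 1L), grid = grid,
                  brainSemiaxes = bs, tumorCenter = bc + off,
                  tumorSemiaxes = semi, hypoFraction = hf, ...)
    })
  })
}

## Deterministic quasi-uniform directions on the unit sphere.
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(th), r * sin(th), z)
}

## Largest brain-ellipsoid inequality value attained on the sampled tumor
## surface: <= 1 means the tumor sits inside the brain.
surfaceMaxRadius2 <- function(off, semi, bs, dirs) {
  pts <- sweep(dirs, 2, semi, "*")
  pts <- sweep(pts, 2, off, "+")
  max(rowSums(sweep(pts, 2, bs, "/")^2))
}
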