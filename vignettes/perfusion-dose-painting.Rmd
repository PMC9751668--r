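---
title: "Perfusion-guided dose painting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion-guided dose painting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfpaint)
```

## The problem

Large brain metastases are heterogeneous: regions of low cerebral blood
flow (CBF) are hypoxic or potentially hypoxic, and hypoxia confers
radioresistance — the isoeffective dose under hypoxia can be several-fold
higher than under normoxia. Arterial spin labeling (ASL) MR perfusion
measures CBF quantitatively and without contrast, so it can delineate the
radioresistant subvolume non-invasively. *Dose painting* then prescribes a
higher dose to that subvolume (a simultaneous integrated boost, SIB)
while the rest of the target keeps the conventional prescription, aiming
to escalate where escalation matters without raising the dose to organs
at risk (OARs).

`perfpaint` implements this workflow end to end as a reproducible,
seeded simulation: synthetic single-metastasis head phantoms, CBF
threshold segmentation, margin-based target derivation, a synthetic dose
model with the three plan styles, dose-volume-histogram (DVH) metrics,
and cohort statistics.

## Segmentation model

Within the contoured gross tumor volume (GTV), voxels are classified
relative to the within-GTV maximum CBF estimate $M$:

* **nonperfused** — CBF below an absolute necrosis floor (default
  1 ml/100g/min), i.e. necrotic tissue;
* **hypoperfused** — CBF at or above the floor but strictly below
  $T = 0.25\,M$ (one quarter of the maximum);
* **hyperperfused** — CBF at or above $T$.

The boost subvolume GTV\_H is the hypoperfused compartment plus, by
default, the nonperfused compartment: the defining rule "strictly less
than 25% of the maximum" subsumes necrotic voxels, and boosting a
necrotic core is dosimetrically harmless because it is surrounded by the
boost region anyway. A flag (`includeNonperfused = FALSE`) excludes it.
Ties at exactly $T$ are hyperperfused. Because the threshold is relative,
the segmentation is invariant under positive rescaling of the CBF map
(when the absolute floor is rescaled alongside, or no voxels sit near
it).

$M$ defaults to the raw within-GTV maximum — the literal rule. A single
noisy voxel can inflate a raw maximum, so `maxPercentile` (e.g. 99)
substitutes an upper percentile; the default stays with the literal rule
so the package reproduces the published behaviour unless the user opts
out.

## Target geometry

PTV = GTV + 5 mm, PTV\_H = GTV\_H + 3 mm, PTV\_N = PTV − PTV\_H. Margin
expansion is defined voxel-exactly: an output voxel is a member iff its
centre lies within the margin (inclusive, Euclidean, physical mm) of
some member voxel centre, with anisotropic spacing respected. The
implementation is a structuring-element dilation over every voxel offset
whose physical length is within the margin — this *is* the definition,
evaluated on a cropped bounding box; the test suite additionally checks
it against a brute-force all-pairs distance oracle on small grids.
Because GTV\_H ⊆ GTV and 3 mm ≤ 5 mm, PTV\_H is nested in PTV and
PTV\_H/PTV\_N partition PTV exactly (enforced by class validity).

Both targets are clipped to the brain outline by default, standard
planning practice for intracranial targets; `clipToBrain = FALSE`
disables it. Whether to clip at the skull is a genuinely open choice —
the clip is the package's documented default, not a claim about any
clinical protocol.

## The synthetic phantom

The phantom generator stands in for patient imaging. It emulates:

* a brain ellipsoid (62% of the grid half-extent per axis);
* one tumor ellipsoid with volume drawn log-uniformly in 8.4–118 cm³.
  The log-uniform draw is a deliberate choice: the observed cohort mean
  (34.5 cm³) sits far below the midpoint of the range, indicating right
  skew, and the log-uniform mean (≈ 41 cm³) lands within a factor
  of 2 of it;
* internal perfusion layering by *normalized ellipsoidal radius* $r$:
  nonperfused core ($r <$ `coreFraction`), hypoperfused mantle, and
  hyperperfused rim ($r \ge$ `mantleFraction`). Layering by ellipsoidal
  radius (not Euclidean distance) makes compartment volumes analytic:
  the hypoperfused-plus-nonperfused fraction equals `mantleFraction`³
  exactly, so `mantleFraction = 0.493^(1/3)` reproduces the 49.3%
  hypoperfused fraction of the reference cohort, and per-subject
  fractions are drawn N(0.493, 0.06) truncated to (0.25, 0.75);
* additive Gaussian CBF noise (SD 2 ml/100g/min), clipped at zero —
  the simplest noise model satisfying CBF nonnegativity;
* a fixed atlas of ellipsoidal OARs (eyes with embedded lenses,
  elongated optic-nerve ellipsoids, brainstem) positioned relative to
  the brain. Only maximum-dose sampling is needed of them, so
  anatomical fidelity is deliberately minimal.

Compartment CBF magnitudes (rim 100, mantle 15, core 0.3, background
40 ml/100g/min) are configurable stand-ins: no per-compartment reference
values exist for metastases, so they were chosen once as physiologically
plausible levels that keep the mantle below the 25% threshold with wide
noise margin (the class validity enforces rim > 4 × mantle). The default
grid is 256 × 256 × 64 at (1, 1, 3) mm, mirroring a 256-matrix MR
acquisition with 3 mm slices; examples and tests run on coarser grids
(96 × 96 × 48 at (2, 2, 3) mm and smaller), which keeps voxelization
error in volume fractions near 1% while making a full cohort run a
matter of seconds.

What the phantom does **not** emulate: ASL acquisition physics and
labeling-delay effects, irregular (non-ellipsoidal) tumor shapes,
multifocal disease, perfusion texture within compartments, and skull /
scalp anatomy. Passing tests therefore demonstrate correctness of the
*computational pipeline* under controlled conditions, not clinical
validity on real images.

## The synthetic dose model

The dose model replaces a commercial inverse optimizer and dose engine.
It reproduces the *structure* of the three plans, not optimized fluence:

* **plan1** — 60 Gy to PTV, global maximum-dose cap 66 Gy (110%);
* **plan2** — 60 Gy to PTV\_N, SIB 72 Gy to PTV\_H, cap 79 Gy (110%);
* **plan3** — as plan2 with no cap; a seeded hotspot field (amplitude
  6 Gy, 4 mm correlation) inside PTV\_H survives, emulating the hot
  spots an unconstrained optimizer tolerates.

Pipeline, in order: (1) a prescription objective map painted on targets
*dilated by 2σ* — the dilation plays the role the optimizer plays in a
real plan, keeping the blurred plateau over the target (its rim bleeding
72 Gy into PTV\_N mirrors the unavoidable gradient around a boost);
(2) Gaussian penumbra blur (σ = 3 mm, physical units, anisotropy-aware,
FFT-based); (3) a wide-Gaussian low-dose bath (amplitude 30% of the base
prescription, σ = 40 mm) normalized against the base-prescription field,
giving OARs distance-dependent dose that rises only a few percent when
just the subvolume is boosted; (4) the seeded hotspot; (5) one-sided
per-target renormalization: if the coverage dose (D95% by default) of a
target falls below its prescription the dose is scaled up — globally for
the base target, locally (weighted by a blurred boost-target indicator)
for the boost — and never scaled down, since the goal is "at least the
prescription to 95% of the target"; (6) with a cap set, a soft-knee
clamp compresses values above the highest prescription exponentially
toward the cap, which is approached but never exceeded; normalization is
re-checked for at most 10 rounds and an irreconcilable cap/coverage
conflict is an explicit error.

Numerical notes: the blur kernel is separable, wrapped and unit-sum, so
FFT wrap-around only matters within the kernel's far tail (negligible
for centred anatomy); σ = 0 is special-cased to the exact identity; the
clamp leaves values at or below the knee untouched, so a coverage level
normalized at the prescription survives capping; the renormalization
scale is nudged by 1 part in 10⁹ past floating-point ties at the rank
voxel.

Dose is computed on the image grid rather than a separate 2.5 mm dose
grid: the metrics are grid-agnostic and a shared grid keeps mask algebra
exact. All downstream metrics would apply unchanged to a resampled dose
grid read from NIfTI.

## DVH metrics

* **Dp%** — descending-sort rank convention: rank ⌈p/100 · N⌉ of the
  sorted voxel doses, no interpolation. Exactly testable; D2% ≥ D50% ≥
  D98% always.
* **Dmean** — the published definition of the "mean" as the dose to 50%
  of the volume is the *median* (D50%), which conflicts with the
  conventional arithmetic mean. Both are computed and reported under
  explicit names; `Dmean` is the arithmetic mean.
* **Coverage** — percent of the structure at or above the prescription.
* **CI** — Paddick conformity index
  $(V_{t,ref}/V_t)\cdot(V_{t,ref}/V_{ref})$ in [0, 1]; $V_{ref}$ is
  evaluated within the brain mask so background air cannot inflate
  conformity.
* **IOA** — index of achievement,
  $1 + \sum_K \sum_j ((D_j - D_{K,RX})/D_{K,RX})^2\,
  \mathrm{dDVH}_{K}(D_j)/V_K$, evaluated on differential-DVH bin centres
  (default 0.05 Gy bins); `binWidthGy = 0` gives the exact voxel-wise
  sum, which serves as the oracle in tests (binned and voxel-wise agree
  to < 10⁻³ at the default width). IOA ≥ 1, with 1 meaning the dose
  equals the prescription throughout.

DVH bins are left-closed, so a voxel exactly at a bin edge counts toward
"receiving at least" that edge — required for the cumulative curve to
start at 1 and step correctly at uniform doses.

Per-structure prescriptions for coverage/CI/IOA follow the plan: the
conventional plan evaluates everything at 60 Gy; the painting plans
evaluate PTV\_H at 72 Gy and PTV/PTV\_N at 60 Gy. What prescription a
boost target "should" have under the conventional plan is genuinely
ambiguous (none is prescribed); evaluating it at the base dose is the
documented default and the assignment is fully configurable through
`indexOfAchievement()`.

## Cohort statistics

Plan comparisons use one-way ANOVA (F, p) with Fisher's LSD pairwise
tests built on the pooled within-group mean square — no further
multiplicity correction, matching standard LSD usage. Means are reported
with the sample (n−1) SD. Between-plan increments are
$100\,(b-a)/a$ computed on the plan means (a per-subject mode exists),
rounded to 2 decimals only at report time. Applying independent-groups
ANOVA to same-subject plans ignores the pairing; the package implements
the stated analysis and flags the caveat here.

## Reproducibility

Every random draw (cohort sampling, CBF noise, hotspot fields) derives
from explicit integer seeds, and library code restores the caller's RNG
state. A three-subject end-to-end run reproduces its output CSVs
byte-for-byte under a fixed seed; `runPipeline()` writes a manifest with
the package version, seed and a configuration hash.

```{r, eval = FALSE}
res <- runPipeline(pipelineConfig(seed = 1, nSubjects = 3,
                                  grid = imageGrid(c(96, 96, 48), c(2, 2, 3))))
res$summary
```

## Known limitations

* The dose model is a labelled surrogate: absolute OAR doses and CI
  levels are plausible but not comparable to optimizer output; only the
  prescription/cap/coverage structure and relative (between-plan)
  behaviour are meaningful.
* Ellipsoidal phantoms understate the irregularity of real boost
  subvolumes, so conformity indices run higher than published clinical
  values.
* The segmentation assumes the GTV contour is given; GTV delineation
  from contrast-enhanced T1 is out of scope.
* Single lesions only; no registration (all volumes share one grid by
  construction).
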