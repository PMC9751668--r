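# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute force / direct summation) and never call the code paths they check.

# Small anisotropic grid typical of the test suite.
testGrid <- function(shape = c(96, 96, 48), spacing = c(2, 2, 3))
  imageGrid(shape, spacing)

# A centred, noise-controllable phantom on a fine (1,1,3) mm grid, with the
# brain chosen large enough to contain the tumor (eyes may fall off-grid;
# irrelevant where OARs are unused).
finePhantomSpec <- function(seed = 1, noiseSD = 0, hypoFraction = 0.493,
                            coreFraction = 0.35 * hypoFraction^(1 / 3),
                            tumorSemiaxes = c(20, 15, 10), ...) {
  g <- imageGrid(c(64, 56, 26), c(1, 1, 3))
  phantomSpec(seed = seed, grid = g, brainSemiaxes = c(30, 26, 36),
              tumorCenter = gridCenter(g), tumorSemiaxes = tumorSemiaxes,
              hypoFraction = hypoFraction, coreFraction = coreFraction,
              noiseSD = noiseSD, ...)
}

# Default-proportioned phantom with room for the OAR atlas.
atlasPhantom <- function(seed = 7, grid = testGrid())
  generatePhantom(phantomSpec(seed = seed, grid = grid,
                              tumorSemiaxes = c(20, 15, 10)))

# Brute-force margin expansion: a voxel is in the result iff its centre is
# within marginMM of some member voxel centre — checked against every
# member voxel.
bruteForceExpand <- function(mask, marginMM) {
  grid <- mask@grid
  sp <- grid@spacing
  idx <- which(mask@member, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, sp, "*")
  all <- as.matrix(expand.grid(i = seq_len(grid@shape[1]),
                               j = seq_len(grid@shape[2]),
                               k = seq_len(grid@shape[3])))
  allp <- sweep(all - 1, 2, sp, "*")
  m2 <- marginMM^2 + 1e-9
  member <- logical(nrow(all))
  for (r in seq_len(nrow(pts))) {
    d2 <- (allp[, 1] - pts[r, 1])^2 + (allp[, 2] - pts[r, 2])^2 +
      (allp[, 3] - pts[r, 3])^2
    member <- member | d2 <= m2
  }
  out <- array(FALSE, dim = grid@shape)
  out[all[member, , drop = FALSE]] <- TRUE
  out
}

# Random blobby mask on a small grid (seeded): union of a few ellipsoids.
randomMask <- function(grid, seed, nBlobs = 3) {
  set.seed(seed)
  member <- array(FALSE, dim = grid@shape)
  ext <- gridExtent(grid)
  for (b in seq_len(nBlobs)) {
    ctr <- grid@origin + runif(3, 0.3, 0.7) * ext
    semi <- runif(3, 0.08, 0.2) * ext
    member <- member | ellipsoidMask(grid, ctr, semi)@member
  }
  structureMask(grid, "blob", member)
}

# Block-mask TargetSet for dose-model tests: an outer PTV box with an inner
# PTV_H box.
blockTargets <- function(grid = imageGrid(c(40, 40, 20), c(2, 2, 3))) {
  p <- array(FALSE, dim = grid@shape)
  p[11:30, 11:30, 6:15] <- TRUE
  h <- array(FALSE, dim = grid@shape)
  h[16:25, 16:25, 9:12] <- TRUE
  new("TargetSet",
      ptv = structureMask(grid, "PTV", p),
      ptvH = structureMask(grid, "PTV_H", h),
      ptvN = structureMask(grid, "PTV_N", p & !h))
}

brainAll <- function(grid)
  structureMask(grid, "brain", array(TRUE, dim = grid@shape))
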