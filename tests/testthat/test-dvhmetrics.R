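uniformDose <- function(grid, value)
  doseGrid(grid, array(value, dim = grid@shape))

test_that("DVH of a uniform dose is a step function and conserves volume", {
  g <- imageGrid(c(10, 10, 4), c(2, 2, 3))
  m <- randomMask(g, seed = 11)
  dvh <- computeDVH(uniformDose(g, 60), m, binWidthGy = 0.5)
  expect_equal(sum(dvh@diffVolume), maskVolume(m))
  below <- dvh@edges <= 60
  expect_true(all(dvh@cumFraction[below] == 1))
  expect_true(all(dvh@cumFraction[!below] == 0))
})

test_that("two-level dose splits the DVH at the mid dose", {
  g <- imageGrid(c(2, 1, 1), c(10, 10, 10))
  m <- structureMask(g, "two", array(TRUE, dim = c(2, 1, 1)))
  d <- doseGrid(g, array(c(60, 72), dim = c(2, 1, 1)))
  dvh <- computeDVH(d, m, binWidthGy = 1)
  vv <- voxelVolume(g) / 1000
  expect_equal(sum(dvh@diffVolume > 0), 2)
  expect_equal(unname(dvh@diffVolume[dvh@diffVolume > 0]), c(vv, vv))
  atEdge <- function(e) dvh@cumFraction[which(dvh@edges == e)]
  expect_equal(atEdge(66), 0.5)
})

test_that("DVH volumes sum to the structure volume on random doses", {
  g <- imageGrid(c(16, 12, 6), c(1.7, 2.1, 3))
  m <- randomMask(g, seed = 3)
  set.seed(42)
  d <- doseGrid(g, array(runif(prod(g@shape), 0, 80), dim = g@shape))
  for (bw in c(0.05, 0.5, 2)) {
    dvh <- computeDVH(d, m, bw)
    expect_equal(sum(dvh@diffVolume), maskVolume(m), tolerance = 1e-12)
    expect_true(all(diff(dvh@cumFraction) <= 1e-12))
    expect_equal(dvh@cumFraction[1], 1)
  }
  expect_error(computeDVH(d, structureMask(g, "e",
    array(FALSE, dim = g@shape))), "empty")
})

test_that("Dp% follows the descending-rank convention", {
  expect_equal(doseAtVolume(1:100, 2), 99)
  expect_equal(doseAtVolume(1:100, 98), 3)
  expect_equal(doseAtVolume(1:100, 50), 51)
  expect_equal(doseAtVolume(rep(42.5, 17), 2), 42.5)
  expect_equal(doseAtVolume(rep(42.5, 17), 98), 42.5)
  expect_error(doseAtVolume(1:10, 0), "in \\(0, 100\\)")
})

test_that("near-max, median and near-min doses are ordered on random grids", {
  g <- imageGrid(c(12, 12, 8), c(2, 2, 3))
  m <- randomMask(g, seed = 8)
  for (s in 1:5) {
    set.seed(s)
    d <- doseGrid(g, array(rgamma(prod(g@shape), 8, 0.15), dim = g@shape))
    d2 <- doseAtVolume(d, 2, m); d50 <- doseAtVolume(d, 50, m)
    d98 <- doseAtVolume(d, 98, m)
    expect_gte(d2, d50); expect_gte(d50, d98)
  }
})

test_that("mean dose equals the brute-force average", {
  g <- imageGrid(c(8, 8, 4), c(1, 1, 3))
  m <- randomMask(g, seed = 2)
  set.seed(7)
  arr <- array(runif(prod(g@shape), 0, 70), dim = g@shape)
  d <- doseGrid(g, arr)
  expect_equal(meanDose(d, m), sum(arr[m@member]) / sum(m@member))
  half <- doseGrid(g, array(rep(c(60, 72), each = prod(g@shape) / 2),
                            dim = g@shape))
  whole <- structureMask(g, "all", array(TRUE, dim = g@shape))
  expect_equal(meanDose(half, whole), 66)
})

test_that("target coverage counts the fraction at or above the level", {
  g <- imageGrid(c(10, 10, 2), c(2, 2, 3))
  whole <- structureMask(g, "all", array(TRUE, dim = g@shape))
  expect_equal(targetCoverage(uniformDose(g, 61), whole, 60), 100)
  arr <- array(60, dim = g@shape); arr[1:5, , ] <- 59
  expect_equal(targetCoverage(doseGrid(g, arr), whole, 60), 50)
})

test_that("conformity index matches hand-computed block cases", {
  g <- imageGrid(c(20, 20, 5), c(1, 1, 1))
  tgt <- array(FALSE, dim = c(20, 20, 5)); tgt[1:10, 1:10, 1] <- TRUE
  target <- structureMask(g, "t", tgt)
  # isodose == target: perfect conformity
  d <- array(0, dim = c(20, 20, 5)); d[tgt] <- 60
  expect_equal(conformityIndex(doseGrid(g, d), target, 60), 1)
  # V_t = 100, V_t,ref = 80, V_ref = 160: CI = 0.8 * 0.5 = 0.40
  d2 <- array(0, dim = c(20, 20, 5))
  d2[1:8, 1:10, 1] <- 60          # 80 covered target voxels
  d2[11:18, 1:10, 1] <- 60        # 80 covered voxels outside the target
  expect_equal(conformityIndex(doseGrid(g, d2), target, 60), 0.40)
  # isodose missing the target entirely
  d3 <- array(0, dim = c(20, 20, 5)); d3[11:20, 11:20, 2] <- 60
  expect_equal(conformityIndex(doseGrid(g, d3), target, 60), 0)
  expect_equal(conformityIndex(doseGrid(g, array(0, dim = c(20, 20, 5))),
                               target, 60), 0)
})

test_that("index of achievement matches hand and voxel-wise computations", {
  g <- imageGrid(c(10, 10, 2), c(2, 2, 3))
  whole <- structureMask(g, "t", array(TRUE, dim = g@shape))
  # exact prescription everywhere: IOA = 1
  expect_equal(indexOfAchievement(uniformDose(g, 60),
    list(list(mask = whole, rx = 60))), 1, tolerance = 1e-6)
  # half at rx, half at 1.2 rx: IOA = 1 + 0.5 * 0.2^2 = 1.02
  arr <- array(60, dim = g@shape); arr[, 6:10, ] <- 72
  ioa <- indexOfAchievement(doseGrid(g, arr),
                            list(list(mask = whole, rx = 60)))
  expect_equal(ioa, 1.02, tolerance = 1e-3)
  expect_gte(ioa, 1)
})

test_that("binned IOA converges to the voxel-wise oracle", {
  g <- imageGrid(c(12, 12, 6), c(2, 2, 3))
  m <- randomMask(g, seed = 21)
  set.seed(13)
  arr <- array(rnorm(prod(g@shape), 66, 4), dim = g@shape)
  arr <- pmax(arr, 0)
  d <- doseGrid(g, arr)
  # independent voxel-wise oracle computed inline
  oracle <- 1 + mean(((arr[m@member] - 66) / 66)^2)
  binned <- indexOfAchievement(d, list(list(mask = m, rx = 66)),
                               binWidthGy = 0.05)
  expect_lt(abs(binned - oracle), 1e-3)
  exact <- indexOfAchievement(d, list(list(mask = m, rx = 66)),
                              binWidthGy = 0)
  expect_equal(exact, oracle, tolerance = 1e-12)
})

test_that("plan metrics table contains every structure and metric", {
  x <- local({
    ph <- atlasPhantom()
    gtv <- ph$structures[["GTV"]]
    lab <- classifyPerfusion(ph$cbf, gtv)
    tg <- deriveTargets(gtv, extractGTVH(lab), ph$structures[["brain"]])
    plan <- planPreset("plan2", seed = 2)
    d <- simulatePlanDose(tg, ph$structures[["brain"]], plan)
    oars <- ph$structures@masks[oarConstraints()$name]
    planMetrics(d, tg, ph$structures[["brain"]], plan, oars = oars)
  })
  for (st in c("PTV", "PTV_H", "PTV_N"))
    expect_setequal(x$metric[x$structure == st],
      c("D2", "D98", "D50", "Dmean", "coverage", "CI", "IOA", "volume_cc"))
  expect_equal(sum(x$metric == "Dmax"), 7)
  d2 <- x$value[x$metric == "D2"]; d50 <- x$value[x$metric == "D50"]
  d98 <- x$value[x$metric == "D98"]
  expect_true(all(d2 >= d50 & d50 >= d98))
  ci <- x$value[x$metric == "CI"]
  expect_true(all(ci >= 0 & ci <= 1))
  expect_true(all(x$value[x$metric == "IOA"] >= 1))
})
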