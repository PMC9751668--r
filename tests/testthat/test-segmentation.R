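lineMap <- function(vals) {
  g <- imageGrid(c(length(vals), 1, 1), c(1, 1, 1))
  list(cbf = perfusionMap(g, array(vals, dim = c(length(vals), 1, 1))),
       gtv = structureMask(g, "GTV", array(TRUE, dim = c(length(vals), 1, 1))),
       grid = g)
}

test_that("threshold rule labels voxels non/hypo/hyper as specified", {
  m <- lineMap(c(100, 30, 24, 0))
  lab <- classifyPerfusion(m$cbf, m$gtv, segmentationConfig())
  expect_equal(lab@maxCBF, 100)
  expect_equal(lab@threshold, 25)
  expect_equal(as.vector(lab@labels), c(1L, 1L, 2L, 3L))

  # ties at exactly T are hyperperfused (strict "less than" rule)
  m2 <- lineMap(c(100, 25, 24.999, 5))
  lab2 <- classifyPerfusion(m2$cbf, m2$gtv)
  expect_equal(as.vector(lab2@labels), c(1L, 1L, 2L, 2L))

  # uniform map: everything hyper
  m3 <- lineMap(rep(50, 6))
  lab3 <- classifyPerfusion(m3$cbf, m3$gtv)
  expect_true(all(lab3@labels == 1L))
})

test_that("degenerate inputs are rejected", {
  m <- lineMap(c(0, 0, 0, 0))
  expect_error(classifyPerfusion(m$cbf, m$gtv), "zero")
  empty <- structureMask(m$grid, "GTV", array(FALSE, dim = c(4, 1, 1)))
  expect_error(classifyPerfusion(m$cbf, empty), "empty")
})

test_that("GTV_H extraction honours the nonperfused flag", {
  m <- lineMap(c(100, 30, 24, 0))
  lab <- classifyPerfusion(m$cbf, m$gtv)
  expect_equal(sum(extractGTVH(lab, segmentationConfig())@member), 2)
  expect_equal(sum(extractGTVH(lab,
    segmentationConfig(includeNonperfused = FALSE))@member), 1)
  expect_true(maskContains(m$gtv, extractGTVH(lab)))
})

test_that("labels partition the GTV exactly", {
  ph <- atlasPhantom()
  lab <- classifyPerfusion(ph$cbf, ph$structures[["GTV"]])
  inGTV <- ph$structures[["GTV"]]@member
  expect_true(all(lab@labels[inGTV] %in% 1:3))
  expect_true(all(lab@labels[!inGTV] == 0L))
  rep <- compartmentReport(lab)
  expect_equal(sum(rep$voxels), sum(inGTV))
  expect_equal(sum(rep$fraction_of_gtv), 1)
})

test_that("segmentation is invariant to positive rescaling of the CBF map", {
  ph <- atlasPhantom()
  gtv <- ph$structures[["GTV"]]
  lab1 <- classifyPerfusion(ph$cbf, gtv)
  for (k in c(0.01, 3.7, 1000)) {
    scaled <- perfusionMap(ph$cbf@grid, ph$cbf@values * k)
    labk <- classifyPerfusion(scaled, gtv,
      segmentationConfig(necrosisFloor = k * 1))
    expect_identical(labk@labels, lab1@labels)
  }
})

test_that("raising the threshold fraction never shrinks GTV_H", {
  ph <- atlasPhantom()
  gtv <- ph$structures[["GTV"]]
  prev <- 0
  for (f in c(0.1, 0.25, 0.4, 0.6, 0.9)) {
    cfg <- segmentationConfig(thresholdFraction = f)
    n <- sum(extractGTVH(classifyPerfusion(ph$cbf, gtv, cfg), cfg)@member)
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("a phantom built for a 49.3% hypoperfused fraction segments to it", {
  spec <- finePhantomSpec(noiseSD = 0, hypoFraction = 0.493)
  ph <- generatePhantom(spec)
  lab <- classifyPerfusion(ph$cbf, ph$structures[["GTV"]])
  gtvH <- extractGTVH(lab)
  frac <- sum(gtvH@member) / sum(ph$structures[["GTV"]]@member)
  expect_lt(abs(frac - 0.493), 0.02)
})

test_that("cohort-mean hypoperfused fraction lands near 49.3%", {
  g <- imageGrid(c(64, 64, 32), c(2.5, 2.5, 4))
  specs <- sampleCohort(50, seed = 2024, grid = g)
  fr <- vapply(specs, function(s) {
    ph <- generatePhantom(s)
    lab <- classifyPerfusion(ph$cbf, ph$structures[["GTV"]])
    sum(extractGTVH(lab)@member) / sum(ph$structures[["GTV"]]@member)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.493), 0.05)
})
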