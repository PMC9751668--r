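planTargets <- function() {
  ph <- atlasPhantom()
  gtv <- ph$structures[["GTV"]]
  lab <- classifyPerfusion(ph$cbf, gtv)
  tg <- deriveTargets(gtv, extractGTVH(lab), ph$structures[["brain"]])
  list(ph = ph, tg = tg, brain = ph$structures[["brain"]])
}

test_that("the no-blur limit reproduces the objective map exactly", {
  tg <- blockTargets()
  plan <- planPreset("plan3", penumbraSigma = 0, hotspotAmplitude = 0)
  d <- simulatePlanDose(tg, brainAll(tg@ptv@grid), plan)
  expect_true(all(d@values[tg@ptvH@member] == 72))
  expect_true(all(d@values[tg@ptvN@member] == 60))
})

test_that("capped plans respect their maximum dose and coverage goals", {
  x <- planTargets()
  d1 <- simulatePlanDose(x$tg, x$brain, planPreset("plan1", seed = 5))
  expect_lte(max(d1@values), 66)
  expect_gte(targetCoverage(d1, x$tg@ptv, 60), 95)

  d2 <- simulatePlanDose(x$tg, x$brain, planPreset("plan2", seed = 5))
  expect_lte(max(d2@values), 79)
  expect_gte(targetCoverage(d2, x$tg@ptvN, 60), 95)
  expect_gte(targetCoverage(d2, x$tg@ptvH, 72), 95)

  d3 <- simulatePlanDose(x$tg, x$brain, planPreset("plan3", seed = 5))
  expect_gte(targetCoverage(d3, x$tg@ptvH, 72), 95)
  # dose is nonnegative and finite everywhere
  for (d in list(d1, d2, d3)) {
    expect_true(all(is.finite(d@values)))
    expect_gte(min(d@values), 0)
  }
  # dose painting boosts the subvolume: the monotone-boost contract
  expect_gt(meanDose(d2, x$tg@ptvH), meanDose(d1, x$tg@ptvH))
  expect_gt(meanDose(d3, x$tg@ptvH), meanDose(d1, x$tg@ptvH))
})

test_that("plan simulation is deterministic given the seed", {
  x <- planTargets()
  a <- simulatePlanDose(x$tg, x$brain, planPreset("plan3", seed = 9))
  b <- simulatePlanDose(x$tg, x$brain, planPreset("plan3", seed = 9))
  expect_identical(a@values, b@values)
})

test_that("plan spec validity catches inconsistent prescriptions", {
  expect_error(new("PlanSpec", planId = "plan2",
                   prescriptions = c(PTV_N = 60, PTV_H = 72),
                   dmaxCap = 70, fractionDose = 2, penumbraSigma = 3,
                   normalizationCoverage = 0.95, hotspotAmplitude = 0,
                   bgFraction = 0.3, bgSigma = 40, seed = 1L),
               "dmaxCap")
  expect_error(new("PlanSpec", planId = "plan1",
                   prescriptions = c(foo = 60),
                   dmaxCap = 66, fractionDose = 2, penumbraSigma = 3,
                   normalizationCoverage = 0.95, hotspotAmplitude = 0,
                   bgFraction = 0.3, bgSigma = 40, seed = 1L),
               "named")
})

test_that("OAR Dmax report flags limits correctly", {
  g <- imageGrid(c(10, 10, 4), c(2, 2, 3))
  arr <- array(FALSE, dim = c(10, 10, 4))
  arr[3:5, 3:5, 2] <- TRUE
  lens <- structureMask(g, "Lens-L", arr)
  uniform7 <- doseGrid(g, array(7, dim = c(10, 10, 4)))
  rep <- oarDmaxReport(uniform7, list(lens))
  expect_equal(rep$dmax_gy, 7)
  expect_true(rep$pass)

  hot <- array(7, dim = c(10, 10, 4)); hot[4, 4, 2] <- 9
  rep2 <- oarDmaxReport(doseGrid(g, hot), list(lens))
  expect_equal(rep2$dmax_gy, 9)
  expect_false(rep2$pass)

  cold <- structureMask(g, "Eye-L", array(FALSE, dim = c(10, 10, 4)))
  cold@member[9, 9, 4] <- TRUE
  rep3 <- oarDmaxReport(doseGrid(g, array(0, dim = c(10, 10, 4))),
                        list(cold))
  expect_equal(rep3$dmax_gy, 0)
  expect_true(rep3$pass)

  empty <- structureMask(g, "Eye-R", array(FALSE, dim = c(10, 10, 4)))
  rep4 <- oarDmaxReport(uniform7, list(empty))
  expect_true(is.na(rep4$dmax_gy))
  expect_true(is.na(rep4$pass))
})
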