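test_that("increment percentages reproduce hand-derived values", {
  expect_equal(round(incrementPercent(64.42, 77.42), 2), 20.18)
  expect_equal(round(incrementPercent(8.92, 9.39), 2), 5.27)
  for (x in c(0.3, 7, 120)) expect_equal(incrementPercent(x, x), 0)
  expect_error(incrementPercent(0, 5), "nonzero")
  # applying the increment to the reference recovers the comparator
  inc <- incrementPercent(63.43, 75.86)
  expect_equal(63.43 * (1 + inc / 100), 75.86)
})

test_that("one-way ANOVA with LSD matches hand computation and aov", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  res <- anovaLSD(vals, grp)
  expect_equal(res$F, 3)
  expect_equal(res$df, c(2, 6))
  # independent route: stats::aov
  fit <- summary(stats::aov(vals ~ factor(grp)))[[1]]
  expect_equal(res$F, fit[["F value"]][1])
  expect_equal(res$p, fit[["Pr(>F)"]][1])
  expect_equal(nrow(res$pairwise), 3)
})

test_that("identical groups hit the F = 0 degenerate branch", {
  res <- anovaLSD(rep(c(5, 6), 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("two far-separated tight groups give tiny LSD p values", {
  res <- anovaLSD(c(1.0, 1.1, 0.9, 100.0, 100.1, 99.9),
                  rep(c("a", "b"), each = 3))
  expect_lt(res$pairwise$p[1], 1e-3)
  expect_true(res$pairwise$significant[1])
})

test_that("with two groups F equals the squared pooled t", {
  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(7, 10, 2); b <- rnorm(9, 12, 2)
    res <- anovaLSD(c(a, b), rep(c("a", "b"), c(7, 9)))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$pairwise$p[1], tt$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA input validation", {
  expect_error(anovaLSD(1:5, rep("a", 5)), "two groups")
  expect_error(anovaLSD(1:3, c("a", "a", "b")), "at least two values")
})

makeTable <- function(values, plans, subjects,
                      structure = "PTV_H", metric = "Dmean")
  data.frame(subject = subjects, plan = plans, structure = structure,
             metric = metric, value = values)

test_that("cohort summary computes sample statistics and increments", {
  tab <- makeTable(c(10, 20), c("plan1", "plan1"), c("s1", "s2"))
  s <- summarizeCohort(tab)
  expect_equal(s$mean_plan1, 15)
  expect_equal(s$sd_plan1, sd(c(10, 20)))
  expect_equal(round(s$sd_plan1, 2), 7.07)

  # plan2 = 1.2 x plan1 subject-wise: increment of the means is 20%
  v1 <- c(55, 60, 65, 70)
  tab2 <- rbind(makeTable(v1, "plan1", paste0("s", 1:4)),
                makeTable(1.2 * v1, "plan2", paste0("s", 1:4)))
  s2 <- summarizeCohort(tab2)
  expect_equal(s2$pct_1_2, 20)
  s2sub <- summarizeCohort(tab2, incrementsOnMeans = FALSE)
  expect_equal(s2sub$pct_1_2, 20)
  expect_true(s2$p < 0.05 || s2$p >= 0)  # ANOVA ran
})

test_that("cohort summary is invariant to subject order and rejects duplicates", {
  v1 <- c(61, 63, 62); v2 <- c(73, 75, 74); v3 <- c(74, 76, 75)
  tab <- rbind(makeTable(v1, "plan1", paste0("s", 1:3)),
               makeTable(v2, "plan2", paste0("s", 1:3)),
               makeTable(v3, "plan3", paste0("s", 1:3)))
  a <- summarizeCohort(tab)
  b <- summarizeCohort(tab[sample(nrow(tab)), ])
  rownames(b) <- NULL
  expect_equal(a, b)
  expect_error(summarizeCohort(rbind(tab, tab[1, ])), "duplicate")
  expect_equal(a$pct_1_2, incrementPercent(mean(v1), mean(v2)))
  expect_equal(a$pct_1_3, incrementPercent(mean(v1), mean(v3)))
  expect_equal(a$pct_2_3, incrementPercent(mean(v2), mean(v3)))
})

test_that("published-style mean tables round-trip through increments", {
  ref <- referenceCohort("targets")
  d2 <- ref[ref$structure == "PTV" & ref$metric == "D2", ]
  expect_equal(round(incrementPercent(d2$plan1, d2$plan2), 2), 20.18)
  expect_equal(round(incrementPercent(d2$plan1, d2$plan3), 2), 24.05)
})
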