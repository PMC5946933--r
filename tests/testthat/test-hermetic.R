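# Oxygen budgets, depletion statistics, regressions, grain quality.

# Published per-jar means: estimated initial and final O2 volumes (ml) and
# insect counts for the six treatments, with the printed consumption per
# insect and depletion statistics.
jarTable <- data.frame(
  treatment = c("25/1000", "25/500", "50/1000", "50/500", "100/1000",
                "100/500"),
  nInsects  = c(25, 25, 50, 50, 100, 100),
  initialMl = c(95.2, 53.1, 94.7, 52.9, 94.5, 52.5),
  finalMl   = c(12.6, 6.0, 8.8, 1.0, 3.5, 0.6),
  consumed  = c(3.3, 1.9, 1.7, 1.0, 0.9, 0.5),
  daysTo2   = c(13, 11, 12, 8, 6, 5),
  rate      = c(1.92, 2.27, 4.17, 6.25, 16.67, 20))

test_that("oxygen budgets reproduce the printed per-insect consumption", {
  for (i in seq_len(nrow(jarTable))) {
    b <- oxygenBudgetVolumes(jarTable$initialMl[i], jarTable$finalMl[i],
                             jarTable$nInsects[i])
    expect_equal(round(b$consumedPerInsect, 1), jarTable$consumed[i])
    # volume conservation is exact
    expect_identical(b$initialVolume,
                     b$finalVolume + jarTable$nInsects[i] * b$consumedPerInsect)
  }
  # percentage mode: 21% of the air volume is the initial O2 volume
  b <- oxygenBudget(airVolume = 480, initialO2Pct = 21, finalO2Pct = 2.1,
                    nInsects = 50)
  expect_equal(b$initialVolume, 100.8)
  expect_equal(b$finalVolume, 10.08)
  expect_equal(b$consumedPerInsect, (100.8 - 10.08) / 50)

  expect_equal(oxygenBudgetVolumes(50, 50, 25)$consumedPerInsect, 0)
  expect_error(oxygenBudgetVolumes(10, 20, 25), "exceeds initial")
})

test_that("depletion rate statistic matches the printed populations/days", {
  expect_equal(depletionRate(jarTable$nInsects, jarTable$daysTo2),
               jarTable$rate)
  expect_equal(depletionRate(25, 25), 1)
  expect_true(is.na(depletionRate(50, NA)))
  expect_error(depletionRate(0, 5), "positive")
  expect_error(depletionRate(50, 0), "positive")
})

test_that("time to a target O2 level interpolates linearly", {
  days <- 0:10
  o2 <- 21 - 2 * days
  expect_equal(timeToO2Level(days, o2, 5), 8)
  expect_equal(timeToO2Level(days, o2, 2), 9.5)
  # already below at the first observation
  expect_equal(timeToO2Level(1:3, c(1.5, 1.0, 0.5), 2), 0)
  # never reached
  expect_true(is.na(timeToO2Level(1:3, c(20, 18, 16), 5)))
  expect_error(timeToO2Level(c(1, 1, 2), c(3, 2, 1), 2), "ascending")
  expect_error(timeToO2Level(numeric(0), numeric(0), 2), "empty")
})

test_that("weight loss follows the count-and-weigh formula", {
  expect_equal(weightLoss(wu = 100, wd = 8, nu = 100, nd = 10),
               100 * (10 * 100 - 100 * 8) / (100 * 110))  # 1.818...
  expect_equal(round(weightLoss(100, 8, 100, 10), 3), 1.818)
  # no damaged kernels
  expect_equal(weightLoss(100, 0, 100, 0), 0)
  # equal per-grain weights: algebraic zero
  expect_equal(weightLoss(wu = 50, wd = 5, nu = 100, nd = 10), 0)
  expect_warning(wl <- weightLoss(wu = 10, wd = 20, nu = 100, nd = 10),
                 "negative")
  expect_lt(wl, 0)
  expect_error(weightLoss(0, 1, 10, 1), "wu")
  expect_error(weightLoss(10, 0, 0, 0), "no kernels")
})

test_that("germination capacity is the pooled percentage", {
  expect_equal(germinationCapacity(c(25, 25, 25, 25))$percent, 100)
  expect_equal(germinationCapacity(c(23, 23, 23, 23))$percent, 92)
  expect_equal(germinationCapacity(c(0, 0, 0, 0))$percent, 0)
  g <- germinationCapacity(c(20, 25))
  expect_equal(g$percent, 90)
  expect_equal(g$perDish, c(80, 100))
  expect_error(germinationCapacity(c(26, 20)), "exceeds")
})

test_that("activity regression recovers exact lines and satisfies F-R2", {
  des0 <- experimentDesign(replicates = 1, schedule = c(0, 0.5, 1),
                           noiseSd = c(rb = 0, nb = 0, rbimp = 0),
                           rngSeed = 5L)
  recs0 <- generateExperiment(des0)
  co <- defaultActivityCoefficients()
  for (m in c("rb", "nb", "rbimp")) {
    f <- suppressWarnings(suppressMessages(fitActivityRegression(recs0, m)))
    expect_equal(f$slope, co[[m]][["slope"]] * co$scale, tolerance = 1e-6)
    expect_equal(f$intercept, co[[m]][["intercept"]] * co$scale,
                 tolerance = 1e-6)
    expect_lt(f$slope, 0)
    expect_equal(f$rSquared, 1, tolerance = 1e-9)
  }

  # F-R2 identity on noisy fits
  recs <- generateExperiment(experimentDesign(rngSeed = 21L,
                                              schedule = c(0, 0.5, 1, 1.5)))
  for (m in c("rb", "nb", "rbimp")) {
    f <- suppressMessages(fitActivityRegression(recs, m))
    expect_equal(f$fStat,
                 (f$rSquared / (1 - f$rSquared)) * (f$df[2] / f$df[1]),
                 tolerance = 1e-6)
    expect_gt(f$pValue, 0)
    expect_lte(f$pValue, 1)
  }
  expect_error(fitActivityRegression(recs0[1:2, ], "rb"), "at least 3")
})

test_that("fits against residual O2 and depletion are sign-flipped twins", {
  recs <- generateExperiment(experimentDesign(rngSeed = 33L,
                                              schedule = c(0, 0.5, 1)))
  one <- recs[recs$treatmentId == "50/500" & recs$replicate == 1, ]
  fRes <- fitTreatmentRegression(one, x = "residualO2", y = "rb")
  fDep <- fitTreatmentRegression(one, x = "depletion", y = "rb")
  expect_equal(fRes$slope, -fDep$slope, tolerance = 1e-9)
  expect_equal(fRes$rSquared, fDep$rSquared, tolerance = 1e-9)
})

test_that("within-treatment fits report error variance on exact and noisy lines", {
  d <- data.frame(treatmentId = "t", nInsects = 50, replicate = 1,
                  day = 0:4, residualO2 = c(21, 18, 15, 12, 9))
  d$rb <- 2 * d$residualO2 + 1
  f <- suppressWarnings(fitTreatmentRegression(d, x = "residualO2", y = "rb"))
  expect_equal(f$slope, 2, tolerance = 1e-9)
  expect_equal(f$intercept, 1, tolerance = 1e-9)
  expect_equal(f$s2, 0, tolerance = 1e-12)
  expect_equal(f$rSquared, 1, tolerance = 1e-9)

  # noise tuned for an R2 ~ 0.75 regime: sigma^2 = slope^2 var(x) / 3
  set.seed(88)
  x <- seq(20, 2, length.out = 30)
  sigma <- sqrt(4 * var(x) / 3)
  d2 <- data.frame(treatmentId = "t", nInsects = 50, replicate = 1,
                   day = seq_along(x), residualO2 = x,
                   rb = 2 * x + 1 + rnorm(30, 0, sigma))
  f2 <- fitTreatmentRegression(d2, x = "residualO2", y = "rb")
  expect_gte(f2$rSquared, 0.6)
  expect_lte(f2$rSquared, 0.9)
  expect_equal(f2$s, sqrt(f2$s2))

  expect_error(
    fitTreatmentRegression(rbind(d, transform(d, treatmentId = "u")),
                           x = "residualO2", y = "rb"),
    "single treatment")
})

test_that("summaries report means and SEMs by treatment and day", {
  recs <- generateExperiment(experimentDesign(rngSeed = 13L,
                                              schedule = c(0.5, 1, 5)))
  s <- summarizeTreatments(recs)
  expect_true(all(s$n == 3))
  expect_false(any(is.na(s$residualO2Sem)))

  # first reading: every series starts at 21% with under a day of depletion;
  # low-density treatments are still near 20% while the densest has depleted
  # furthest
  first <- s[s$day == 0.5, ]
  expect_true(all(first$residualO2Mean > 10 & first$residualO2Mean < 21))
  low <- first[first$treatmentId %in% c("25/500", "25/1000"), ]
  expect_true(all(low$residualO2Mean > 18.5))
  expect_identical(
    first$treatmentId[which.min(first$residualO2Mean)], "100/500")

  # single replicate: SEM missing
  one <- summarizeTreatments(recs[recs$replicate == 1, ])
  expect_true(all(is.na(one$residualO2Sem)))

  # identical values: SEM exactly 0 (O2 is deterministic across replicates)
  expect_true(all(s$residualO2Sem == 0))
})
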