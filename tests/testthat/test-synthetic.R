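# Synthetic-data generators: kernels, recordings, experiments, grain counts.

test_that("renderKernel honors duration, amplitude and spectral placement", {
  fs <- 44100
  k <- renderKernel(kernelSpec(4000, 1000, 0.005, amplitude = 0.5), fs)
  expect_equal(length(k), 220L)  # round(0.005 * 44100)
  expect_equal(max(abs(samples(k))), 0.5, tolerance = 0.01)

  # zero amplitude renders silence of the right length
  z <- renderKernel(kernelSpec(amplitude = 0), fs)
  expect_true(all(samples(z) == 0))
  expect_equal(length(z), 220L)

  # dominant FFT energy within centerFrequency +/- bandwidth
  for (cf in c(2000, 4000, 6000)) {
    kk <- renderKernel(kernelSpec(cf, 1000, 0.006, decayRate = 800), fs)
    sp <- abs(fft(samples(kk)))^2
    f <- (seq_along(sp) - 1) * fs / length(sp)
    half <- f <= fs / 2
    peak <- f[half][which.max(sp[half])]
    expect_gte(peak, cf - 1000)
    expect_lte(peak, cf + 1000)
  }

  expect_error(kernelSpec(duration = 0.02), "1-10 ms")
  expect_error(kernelSpec(duration = 5e-4), "1-10 ms")
})

test_that("generateRecording places bursts with valid structure and is reproducible", {
  sc <- acousticScenario(duration = 100, burstRate = 0.2, rngSeed = 42L)
  rec <- generateRecording(sc)

  # observed burst count within the Poisson 99% interval around rate*T = 20
  expect_gte(nrow(rec$bursts), qpois(0.005, 20))
  expect_lte(nrow(rec$bursts), qpois(0.995, 20))

  # onsets strictly increasing; each insect onset inside exactly one burst
  expect_true(all(diff(rec$events$onset) > 0))
  ins <- rec$events$onset[rec$events$label == "insect"]
  nIn <- vapply(ins, function(o)
    sum(o >= rec$bursts$start - 1e-9 & o <= rec$bursts$end + 1e-9), 0)
  expect_true(all(nIn == 1))

  # inter-burst gaps exceed the 0.2 s burst criterion; intra gaps below it
  nb <- nrow(rec$bursts)
  expect_true(all(rec$bursts$start[-1] - rec$bursts$end[-nb] > 0.2))
  expect_true(all(rec$bursts$impulseCount >= 3))

  # bit-identical under the same seed
  rec2 <- generateRecording(sc)
  expect_identical(samples(rec$waveform), samples(rec2$waveform))
  expect_identical(rec$events, rec2$events)

  # silent scenario: no events, zero waveform
  quiet <- acousticScenario(duration = 2, burstRate = 0, distractorRate = 0,
                            noiseFloorRms = 0, rngSeed = 1L)
  recQ <- generateRecording(quiet)
  expect_identical(nrow(recQ$events), 0L)
  expect_true(all(samples(recQ$waveform) == 0))

  # infeasible burst rate is rejected
  dense <- acousticScenario(duration = 2, burstRate = 5, rngSeed = 3L)
  expect_error(generateRecording(dense), "burstRate too high")
})

test_that("scenario validation rejects degenerate configurations", {
  expect_error(acousticScenario(impulsesPerBurst = 2:4), ">= 3")
  expect_error(acousticScenario(intraBurstGapRange = c(0.05, 0.25)),
               "intraBurstGapRange")
  # spectrally indistinct distractor kernel is rejected
  expect_error(
    acousticScenario(distractorKernel = kernelSpec(4000, 1000, 0.005)),
    "spectrally")
})

test_that("generateExperiment starts at 21% O2 and inverts the activity model exactly", {
  des <- experimentDesign(replicates = 1, schedule = c(0, 0.5, 1),
                          noiseSd = c(rb = 0, nb = 0, rbimp = 0), rngSeed = 2L)
  recs <- generateExperiment(des)
  co <- defaultActivityCoefficients()

  day0 <- recs[recs$day == 0, ]
  expect_true(all(day0$residualO2 == 21))
  # at zero depletion the transformed burst rate equals the model intercept
  expect_equal(log10(day0$rb / day0$nInsects + 1),
               rep(co$rb[["intercept"]] * co$scale, nrow(day0)),
               tolerance = 1e-12)

  # zero decay: flat 21% series
  flat <- generateExperiment(experimentDesign(
    replicates = 1, schedule = 0:5, o2DecayRatePerInsect = 0, rngSeed = 2L))
  expect_true(all(flat$residualO2 == 21))

  expect_error(experimentDesign(o2DecayRatePerInsect = -1), "non-negative")
})

test_that("denser infestations cross 2% O2 strictly earlier", {
  des <- experimentDesign(rngSeed = 9L)
  recs <- generateExperiment(des)
  one <- recs[recs$replicate == 1, ]
  t2 <- vapply(split(one, one$treatmentId), function(d)
    timeToO2Level(d$day, d$residualO2, 2), 0)
  expect_lt(t2[["100/500"]], t2[["25/1000"]])
  # full ordering follows insect density per ml of air
  dens <- vapply(split(one, one$treatmentId), function(d)
    d$nInsects[1] / d$airVolume[1], 0)
  reached <- !is.na(t2)
  expect_identical(order(t2[reached]), order(-dens[reached]))
})

test_that("generateGrainCounts round-trips through the weight-loss formula", {
  for (loss in c(0.5, 1.0, 2.5, 10)) {
    gc <- generateGrainCounts(loss, nGrains = 250, rngSeed = 7L)
    got <- weightLoss(gc$wu, gc$wd, gc$nu, gc$nd)
    expect_equal(got, loss, tolerance = 0.1)
  }
  # the spec'd case: 1% on 250 kernels lands in [0.9, 1.1]
  gc <- generateGrainCounts(1.0, 250, rngSeed = 11L)
  wl <- weightLoss(gc$wu, gc$wd, gc$nu, gc$nd)
  expect_gte(wl, 0.9)
  expect_lte(wl, 1.1)

  # zero loss: no damaged kernels
  gc0 <- generateGrainCounts(0, 100, rngSeed = 3L)
  expect_identical(gc0$nd, 0L)
  expect_equal(weightLoss(gc0$wu, gc0$wd, gc0$nu, gc0$nd), 0)

  # deterministic under a fixed seed
  expect_identical(generateGrainCounts(2, 250, rngSeed = 5L),
                   generateGrainCounts(2, 250, rngSeed = 5L))

  expect_error(generateGrainCounts(1, nGrains = 5), ">= 10")
  expect_error(generateGrainCounts(-1, 100), "\\[0, 100\\)")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateRecording(acousticScenario(duration = 2, rngSeed = 1L)))
  invisible(generateExperiment(experimentDesign(rngSeed = 1L)))
  invisible(generateGrainCounts(1, 100, rngSeed = 1L))
  expect_identical(.Random.seed, before)
})
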