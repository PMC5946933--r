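# Profile construction, least-squares matching, classification.

oneHot <- function(bin, nBins = 129L) {
  v <- numeric(nBins)
  v[bin] <- 1
  powerSpectrum(v)
}

test_that("buildProfile averages and renormalizes", {
  s1 <- oneHot(10)
  expect_equal(profileSpectrum(buildProfile(list(s1), "p"))@values, s1@values)

  # two identical spectra: profile equals either
  p2 <- buildProfile(list(s1, s1), "p")
  expect_equal(profileSpectrum(p2)@values, s1@values)
  expect_identical(nImpulses(p2), 2L)

  # averaging two disjoint one-hots: half power in each bin
  p3 <- buildProfile(list(oneHot(10), oneHot(20)), "p")
  expect_equal(profileSpectrum(p3)@values[c(10, 20)], c(0.5, 0.5))
  expect_equal(sum(profileSpectrum(p3)@values), 1, tolerance = 1e-12)

  expect_error(buildProfile(list(), "p"), "at least one")
  bad <- powerSpectrum(rep(1, 65))
  expect_error(buildProfile(list(s1, bad), "p"), "mixed bin counts")
})

test_that("SSE is a proper dissimilarity with the one-hot value 2", {
  a <- oneHot(10); b <- oneHot(20)
  expect_equal(spectrumSse(a, b), 2)          # disjoint unit spectra
  expect_equal(spectrumSse(a, a), 0)
  expect_equal(spectrumSse(a, b), spectrumSse(b, a))
  set.seed(1)
  for (i in 1:20) {
    x <- powerSpectrum(runif(129)); y <- powerSpectrum(runif(129))
    expect_gte(spectrumSse(x, y), 0)
    expect_equal(spectrumSse(x, y), spectrumSse(y, x))
  }
})

test_that("matchImpulse picks the argmin profile and applies the threshold", {
  pa <- buildProfile(list(oneHot(10)), "A")
  pb <- buildProfile(list(oneHot(20)), "B")
  m <- matchImpulse(oneHot(10), list(pa, pb))
  expect_identical(m$bestProfile, "A")
  expect_equal(m$sse, 0)
  expect_true(m$isInsect)

  # disjoint spectrum at default threshold: background noise
  m2 <- matchImpulse(oneHot(30), list(pa, pb))
  expect_equal(m2$sse, 2)
  expect_false(m2$isInsect)

  # ties break by list order
  mt <- matchImpulse(oneHot(15), list(pa, pb))
  expect_identical(mt$bestProfile, "A")

  expect_error(matchImpulse(oneHot(1), list()), "at least one")
})

test_that("dB-scale matching is available and ranks profiles consistently", {
  insect <- kernelProfile(kernelSpec(), "insect")
  distractor <- kernelProfile(kernelSpec(600, 800, 0.008, 400), "distractor")
  s <- profileSpectrum(insect)
  m <- matchImpulse(s, list(insect, distractor), sseThreshold = 1,
                    scale = "db")
  expect_identical(m$bestProfile, "insect")
  expect_equal(m$sse, 0)
  # dB SSEs are on their own magnitude: the distractor is still far away
  expect_gt(m$sseAll[["distractor"]], m$sseAll[["insect"]])
})

test_that("lowering the threshold never increases insect labels", {
  rec <- generateRecording(acousticScenario(duration = 30, burstRate = 0.15,
                                            rngSeed = 19L))
  imp <- detectImpulses(rec$waveform)
  profs <- defaultProfiles()
  nMatched <- vapply(c(0.5, 0.1, 0.05, 0.02, 0.005, 0),
                     function(th) sum(classifyImpulses(imp, profs, th)$isInsect),
                     0L)
  expect_true(all(diff(nMatched) <= 0))
})

test_that("classification is invariant to overall amplitude scaling", {
  w <- kernelAt(1.0, noiseRms = 0)
  wHalf <- waveform(samples(w) * 0.5, sampleRate(w))
  profs <- defaultProfiles()
  c1 <- classifyImpulses(detectImpulses(w), profs)
  c2 <- classifyImpulses(detectImpulses(wHalf), profs)
  expect_identical(nrow(c1), nrow(c2))
  expect_equal(c1$sse, c2$sse, tolerance = 1e-9)
  expect_identical(c1$isInsect, c2$isInsect)
})

test_that("a many-impulse profile resembles its generating kernel, not the distractor", {
  sc <- acousticScenario(duration = 62, burstRate = 0.55, distractorRate = 0,
                         rngSeed = 421L)
  rec <- generateRecording(sc)
  imp <- detectImpulses(rec$waveform)
  truth <- rec$events$onset[rec$events$label == "insect"]
  verified <- vapply(impulseOnsets(imp),
                     function(o) any(abs(truth - o) < 0.002), TRUE)
  idx <- which(verified)
  expect_gte(length(idx), 139)
  sp <- impulseSpectra(imp)
  spectra <- lapply(idx[1:139], function(i) powerSpectrum(sp[i, ]))
  prof <- buildProfile(spectra, "insect139", sourceDuration = 62)

  insectRef <- profileSpectrum(kernelProfile(sc@insectKernel))
  distractorRef <- profileSpectrum(kernelProfile(sc@distractorKernel))
  expect_lt(spectrumSse(profileSpectrum(prof), insectRef),
            spectrumSse(profileSpectrum(prof), distractorRef))
})

test_that("classifyImpulses preserves order and handles fixtures end to end", {
  profs <- defaultProfiles()

  # empty input
  empty <- classifyImpulses(detectImpulses(waveform(numeric(44100))), profs)
  expect_identical(nrow(empty), 0L)

  # all-distractor fixture: nothing matched at the calibrated threshold
  scD <- acousticScenario(duration = 30, burstRate = 0, distractorRate = 0.3,
                          rngSeed = 61L)
  recD <- generateRecording(scD)
  clsD <- classifyImpulses(detectImpulses(recD$waveform), profs)
  expect_gt(nrow(clsD), 0L)
  expect_false(any(clsD$isInsect))

  # mixed fixture: insect-labeled onsets sit on ground-truth insect onsets
  scM <- acousticScenario(duration = 60, burstRate = 0.1, rngSeed = 62L)
  recM <- generateRecording(scM)
  clsM <- classifyImpulses(detectImpulses(recM$waveform), profs)
  expect_false(is.unsorted(clsM$onset))
  ins <- clsM$onset[clsM$isInsect]
  truth <- recM$events$onset[recM$events$label == "insect"]
  onTruth <- vapply(ins, function(o) any(abs(truth - o) < 0.002), TRUE)
  expect_true(all(onTruth))
  recall <- mean(vapply(truth, function(o) any(abs(ins - o) < 0.002), TRUE))
  expect_gte(recall, 0.9)
})

test_that("profiles survive a CSV+JSON round trip", {
  prof <- kernelProfile(kernelSpec(), "roundtrip")
  base <- file.path(withr::local_tempdir(), "prof")
  writeProfile(prof, base)
  back <- readProfile(base)
  expect_identical(profileLabel(back), "roundtrip")
  expect_equal(profileSpectrum(back)@values, profileSpectrum(prof)@values,
               tolerance = 1e-12)
  expect_identical(nImpulses(back), 1L)
})
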