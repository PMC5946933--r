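#!/usr/bin/env Rscript
# Regenerates the two bundled synthetic reference profiles in inst/extdata.
# Each profile is the average of spectra of impulses detected in a synthetic
# recording and verified against the generator's ground truth: profile A
# averages 139 impulses from a 62-s recording, profile B 33 impulses from a
# 20-s recording of a second, slightly different infestation.
suppressMessages(library(grainAcoustics))

buildVerifiedProfile <- function(scenario, nImpulses, label) {
  rec <- generateRecording(scenario)
  imp <- detectImpulses(rec$waveform)
  truth <- rec$events$onset[rec$events$label == "insect"]
  verified <- vapply(impulseOnsets(imp),
                     function(o) any(abs(truth - o) < 0.002), TRUE)
  idx <- which(verified)
  if (length(idx) < nImpulses)
    stop(sprintf("only %d verified impulses for '%s' (need %d)",
                 length(idx), label, nImpulses))
  idx <- idx[seq_len(nImpulses)]
  sp <- impulseSpectra(imp)
  spectra <- lapply(idx, function(i)
    powerSpectrum(sp[i, ], nFft = imp@nFft, sampleRate = sampleRate(rec$waveform)))
  buildProfile(spectra, label, sourceDuration = duration(rec$waveform))
}

scA <- acousticScenario(duration = 62, burstRate = 0.55, distractorRate = 0,
                        rngSeed = 421L)
profA <- buildVerifiedProfile(scA, 139, "wheat_soryzae_A_synthetic")

scB <- acousticScenario(duration = 20, burstRate = 0.45, distractorRate = 0,
                        insectKernel = kernelSpec(centerFrequency = 4300,
                                                  bandwidth = 1000,
                                                  duration = 0.004,
                                                  decayRate = 1200,
                                                  amplitude = 0.5),
                        rngSeed = 422L)
profB <- buildVerifiedProfile(scB, 33, "wheat_soryzae_B_synthetic")

outDir <- file.path("inst", "extdata")
dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
writeProfile(profA, file.path(outDir, "profile_a_synthetic"))
writeProfile(profB, file.path(outDir, "profile_b_synthetic"))
cat("wrote profiles:", profileLabel(profA), "and", profileLabel(profB), "\n")
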