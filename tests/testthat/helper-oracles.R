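# Independent oracles and small fixture builders used across test files.

# Brute-force burst scanner: examines every index window (i, j) and keeps it
# iff all consecutive gaps inside are strictly below maxGap, it cannot be
# extended on either side, and it holds at least minCount onsets. O(n^2),
# independent of the run-splitting algorithm in groupBursts().
bruteForceBursts <- function(onsets, maxGap = 0.2, minCount = 3) {
  n <- length(onsets)
  out <- data.frame(start = numeric(0), end = numeric(0),
                    impulseCount = integer(0))
  if (n == 0) return(out)
  for (i in seq_len(n)) {
    for (j in i:n) {
      inside <- j == i || all(diff(onsets[i:j]) < maxGap)
      if (!inside) next
      leftMax <- i == 1 || (onsets[i] - onsets[i - 1]) >= maxGap
      rightMax <- j == n || (onsets[j + 1] - onsets[j]) >= maxGap
      if (leftMax && rightMax && (j - i + 1) >= minCount)
        out <- rbind(out, data.frame(start = onsets[i], end = onsets[j],
                                     impulseCount = j - i + 1L))
    }
  }
  out
}

# A kernel placed at a known onset in a noisy (or silent) background.
kernelAt <- function(onsetSec, kern = kernelSpec(), totalSec = 3,
                     noiseRms = 0, fs = 44100, seed = 1L) {
  k <- samples(renderKernel(kern, fs))
  n <- round(totalSec * fs)
  x <- numeric(n)
  i0 <- round(onsetSec * fs) + 1L
  x[i0:(i0 + length(k) - 1L)] <- k
  if (noiseRms > 0) {
    set.seed(seed)
    x <- x + rnorm(n, 0, noiseRms)
  }
  waveform(x, fs)
}

# Profile built directly from a kernel's clean spectrum.
kernelProfile <- function(kern, label = "kernel", fs = 44100) {
  w <- renderKernel(kern, fs)
  buildProfile(list(extractSpectrum(w, 0, duration(w))), label)
}
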