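# Impulse detection: high-pass filter, rectified smoothed envelope, robust
# (median/MAD) threshold, event merging within a dead time, duration gating,
# and per-impulse spectrum extraction.

#' Detection configuration
#'
#' All constants of the envelope detector in one validated object.
#'
#' @param envelopeSmoothing seconds of moving-average smoothing applied to
#'   the rectified signal (default 0.5 ms, short against the 1-10 ms
#'   impulses it must resolve).
#' @param thresholdK event threshold in multiples of the envelope's MAD
#'   above its median (default 8).
#' @param deadTime seconds within which supra-threshold events are merged
#'   into one impulse (default 20 ms; must be >= `maxDuration`).
#' @param minDuration,maxDuration events outside this duration range are
#'   discarded as noise (defaults 0.5 ms and 20 ms: insect impulses are
#'   1-10 ms, and a 2x margin is allowed before discarding).
#' @param highpassCutoff Hz of the 4th-order Butterworth high-pass applied
#'   first (default 200 Hz, suppressing room rumble well below the insect
#'   impulse band); 0 disables filtering.
#' @return A list of class `detectionConfig`.
#' @export
detectionConfig <- function(envelopeSmoothing = 5e-4, thresholdK = 8,
                            deadTime = 0.020, minDuration = 5e-4,
                            maxDuration = 0.020, highpassCutoff = 200) {
  if (minDuration >= maxDuration) stop("minDuration must be < maxDuration")
  if (deadTime < maxDuration) stop("deadTime must be >= maxDuration")
  if (thresholdK <= 0) stop("thresholdK must be positive")
  structure(list(envelopeSmoothing = envelopeSmoothing,
                 thresholdK = thresholdK, deadTime = deadTime,
                 minDuration = minDuration, maxDuration = maxDuration,
                 highpassCutoff = highpassCutoff),
            class = "detectionConfig")
}

highpass <- function(x, cutoff, fs) {
  if (cutoff <= 0) return(x)
  bf <- signal::butter(4, cutoff / (fs / 2), type = "high")
  signal::filtfilt(bf, x)
}

#' Detect candidate insect sound impulses
#'
#' High-pass filters the signal, computes a rectified smoothed envelope,
#' marks samples where the envelope exceeds `median + thresholdK * MAD`,
#' merges supra-threshold runs closer than `deadTime`, discards events whose
#' duration falls outside `[minDuration, maxDuration]`, and attaches each
#' surviving event's normalized power spectrum (see [extractSpectrum()]).
#' A silent (all-zero) signal yields an empty set, not an error.
#'
#' @param w a [Waveform-class].
#' @param config a [detectionConfig()].
#' @param nFft FFT length for impulse spectra (default 256).
#' @return An [ImpulseSet-class], sorted by onset.
#' @export
detectImpulses <- function(w, config = detectionConfig(), nFft = 256L) {
  stopifnot(is(w, "Waveform"))
  if (length(w) == 0) stop("empty waveform")
  fs <- w@sampleRate
  emptySet <- function() new("ImpulseSet", onsets = numeric(0),
                             durations = numeric(0), peaks = numeric(0),
                             spectra = matrix(0, 0, nFft / 2L + 1L),
                             nFft = as.integer(nFft), sampleRate = fs,
                             segmentDuration = duration(w))
  if (all(w@samples == 0)) return(emptySet())

  xf <- highpass(w@samples, config$highpassCutoff, fs)
  half <- max(1L, durationToSamples(config$envelopeSmoothing, fs) %/% 2L)
  env <- movingAverage(abs(xf), half)
  # Robust noise floor; the relative floor keeps the threshold meaningful on
  # (near-)noise-free signals where median and MAD collapse to ~0 and filter
  # ringing would otherwise form one long supra-threshold event.
  thr <- max(stats::median(env) + config$thresholdK * stats::mad(env),
             5e-3 * max(env))
  above <- env > thr
  if (!any(above)) return(emptySet())

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  evStart <- starts[r$values]
  evEnd <- ends[r$values]
  # merge events separated by less than the dead time
  deadSamp <- durationToSamples(config$deadTime, fs)
  if (length(evStart) > 1L) {
    gap <- evStart[-1L] - evEnd[-length(evEnd)]
    newGroup <- c(TRUE, gap >= deadSamp)
    grp <- cumsum(newGroup)
    evStart <- as.integer(tapply(evStart, grp, min))
    evEnd <- as.integer(tapply(evEnd, grp, max))
  }
  durSec <- (evEnd - evStart + 1L) / fs
  keep <- durSec >= config$minDuration & durSec <= config$maxDuration
  evStart <- evStart[keep]
  evEnd <- evEnd[keep]
  if (length(evStart) == 0L) return(emptySet())

  onsets <- (evStart - 1L) / fs
  durs <- (evEnd - evStart + 1L) / fs
  peaks <- vapply(seq_along(evStart),
                  function(i) max(abs(xf[evStart[i]:evEnd[i]])), 0)
  wf <- waveform(xf, fs)
  spectra <- t(vapply(seq_along(evStart), function(i)
    extractSpectrum(wf, onsets[i], durs[i], nFft)@values,
    numeric(nFft / 2L + 1L)))
  new("ImpulseSet", onsets = round(onsets, 4), durations = durs,
      peaks = peaks, spectra = spectra, nFft = as.integer(nFft),
      sampleRate = fs, segmentDuration = duration(w))
}

#' Extract a normalized power spectrum around an impulse
#'
#' Computes a Hann-windowed power spectrum averaged over 50\%-overlapping
#' `nFft`-sample frames covering the impulse (the window is padded
#' symmetrically to at least `nFft` samples, with zero-padding at recording
#' edges), one-sided, normalized to unit total power.
#'
#' @param w a [Waveform-class].
#' @param onset impulse onset in seconds (must lie inside the recording).
#' @param duration impulse duration in seconds.
#' @param nFft points per spectrum (default 256).
#' @return A [Spectrum-class].
#' @export
extractSpectrum <- function(w, onset, duration, nFft = 256L) {
  stopifnot(is(w, "Waveform"))
  fs <- w@sampleRate
  n <- length(w)
  if (onset < 0 || onset > n / fs)
    stop(sprintf("onset %.4f s is outside the recording (0-%.4f s)",
                 onset, n / fs))
  i0 <- durationToSamples(onset, fs) + 1L
  i1 <- min(i0 + max(durationToSamples(duration, fs), 1L) - 1L, n)
  # pad symmetrically to at least nFft samples
  need <- nFft - (i1 - i0 + 1L)
  if (need > 0L) {
    i0 <- i0 - ceiling(need / 2)
    i1 <- i1 + floor(need / 2)
  }
  pre <- max(0L, 1L - i0)
  post <- max(0L, i1 - n)
  x <- c(numeric(pre), w@samples[max(i0, 1L):min(i1, n)], numeric(post))

  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(nFft) / (nFft + 1))
  hop <- nFft %/% 2L
  nFrames <- max(1L, (length(x) - nFft) %/% hop + 1L)
  acc <- numeric(nFft %/% 2L + 1L)
  for (f in seq_len(nFrames)) {
    seg <- x[((f - 1L) * hop + 1L):((f - 1L) * hop + nFft)]
    sp <- abs(stats::fft(seg * hann))^2
    acc <- acc + sp[seq_len(nFft %/% 2L + 1L)]
  }
  tot <- sum(acc)
  if (tot <= 0) stop("window has zero power; no spectrum defined")
  powerSpectrum(acc / tot, nFft = nFft, sampleRate = fs)
}
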