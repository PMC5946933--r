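#' @import methods
NULL

# ---------------------------------------------------------------------------
# Waveform
# ---------------------------------------------------------------------------

#' Sampled audio waveform
#'
#' A mono sampled signal with amplitudes on a dimensionless full scale of
#' \eqn{[-1, 1]} and a fixed sampling rate. This is the raw material of
#' impulse detection; recordings of insect activity in grain are typically
#' captured at 44.1 kHz through a waveguide-mounted acoustic sensor.
#'
#' @slot samples numeric vector of amplitudes; finite, nominally in [-1, 1].
#' @slot sampleRate sampling rate in Hz (> 0).
#' @export
setClass("Waveform",
  representation(samples = "numeric", sampleRate = "numeric"),
  validity = function(object) {
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
      return("sampleRate must be a single positive number")
    if (anyNA(object@samples) || any(!is.finite(object@samples)))
      return("samples must be finite")
    TRUE
  }
)

#' Construct a Waveform
#'
#' @param samples numeric vector of amplitudes in [-1, 1].
#' @param sampleRate sampling rate in Hz; default 44100.
#' @return A [Waveform-class] object.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' duration(w)
#' @export
waveform <- function(samples, sampleRate = 44100) {
  new("Waveform", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate))
}

#' @describeIn waveform number of samples.
#' @param x a Waveform.
#' @export
setMethod("length", "Waveform", function(x) length(x@samples))

#' Waveform accessors
#'
#' @param x a [Waveform-class].
#' @return `samples()` the amplitude vector; `sampleRate()` the rate in Hz;
#'   `duration()` the length in seconds.
#' @export
samples <- function(x) x@samples

#' @rdname samples
#' @export
sampleRate <- function(x) x@sampleRate

#' @rdname samples
#' @export
duration <- function(x) length(x@samples) / x@sampleRate

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.3f s), peak |amp| %.4g\n",
              length(object@samples), object@sampleRate,
              length(object@samples) / object@sampleRate,
              if (length(object@samples)) max(abs(object@samples)) else 0))
})

# ---------------------------------------------------------------------------
# Spectrum
# ---------------------------------------------------------------------------

#' Normalized power spectrum of an impulse
#'
#' One-sided power spectrum on \code{nFft/2 + 1} bins, normalized to unit
#' total power so that matching is invariant to recording gain.
#'
#' @slot values non-negative power per frequency bin; sums to 1.
#' @slot nFft FFT length (default 256 in the analysis pipeline).
#' @slot sampleRate Hz; fixes the bin frequencies.
#' @export
setClass("Spectrum",
  representation(values = "numeric", nFft = "integer", sampleRate = "numeric"),
  validity = function(object) {
    if (length(object@values) != object@nFft / 2L + 1L)
      return("values must have length nFft/2 + 1")
    if (any(object@values < 0)) return("power values must be non-negative")
    if (abs(sum(object@values) - 1) > 1e-9)
      return("power values must sum to 1 (unit total power)")
    if (object@sampleRate <= 0) return("sampleRate must be positive")
    TRUE
  }
)

#' Construct a Spectrum
#'
#' @param values non-negative per-bin power; renormalized to unit total.
#' @param nFft FFT length used; `length(values)` must equal `nFft/2 + 1`.
#' @param sampleRate sampling rate in Hz.
#' @return A [Spectrum-class] object.
#' @export
powerSpectrum <- function(values, nFft = 2L * (length(values) - 1L),
                          sampleRate = 44100) {
  tot <- sum(values)
  if (!is.finite(tot) || tot <= 0)
    stop("spectrum has zero or non-finite total power")
  new("Spectrum", values = as.numeric(values) / tot, nFft = as.integer(nFft),
      sampleRate = as.numeric(sampleRate))
}

#' Bin center frequencies of a Spectrum (Hz)
#' @param s a [Spectrum-class].
#' @export
binFrequencies <- function(s) {
  (seq_len(s@nFft / 2L + 1L) - 1L) * s@sampleRate / s@nFft
}

setMethod("show", "Spectrum", function(object) {
  f <- binFrequencies(object)
  cat(sprintf("Spectrum: %d bins (nFft %d @ %g Hz), peak bin %.0f Hz\n",
              length(object@values), object@nFft, object@sampleRate,
              f[which.max(object@values)]))
})

# ---------------------------------------------------------------------------
# SpectralProfile
# ---------------------------------------------------------------------------

#' Averaged spectral profile of verified insect sound impulses
#'
#' The matching template of the classifier: an arithmetic bin-wise mean of
#' the normalized spectra of impulses verified to be insect sounds,
#' renormalized to unit total power.
#'
#' @slot spectrum the mean [Spectrum-class].
#' @slot nImpulses number of impulses averaged (>= 1).
#' @slot sourceDuration seconds of recording the impulses came from.
#' @slot label profile name used in match results.
#' @export
setClass("SpectralProfile",
  representation(spectrum = "Spectrum", nImpulses = "integer",
                 sourceDuration = "numeric", label = "character"),
  validity = function(object) {
    if (object@nImpulses < 1L) return("nImpulses must be >= 1")
    if (length(object@label) != 1L || is.na(object@label))
      return("label must be a single string")
    TRUE
  }
)

setMethod("show", "SpectralProfile", function(object) {
  cat(sprintf("SpectralProfile '%s': mean of %d impulses over %.1f s\n",
              object@label, object@nImpulses, object@sourceDuration))
})

#' SpectralProfile accessors
#' @param p a [SpectralProfile-class].
#' @return `profileSpectrum()` the mean [Spectrum-class]; `profileLabel()`
#'   the label; `nImpulses()` the number averaged.
#' @export
profileSpectrum <- function(p) p@spectrum

#' @rdname profileSpectrum
#' @export
profileLabel <- function(p) p@label

#' @rdname profileSpectrum
#' @export
nImpulses <- function(p) p@nImpulses

# ---------------------------------------------------------------------------
# ImpulseSet
# ---------------------------------------------------------------------------

#' Detected sound impulses from one analyzed segment
#'
#' Container for the brief (about 1-10 ms) transients found by the envelope
#' detector, each with onset, duration, peak amplitude and a normalized
#' power spectrum (one matrix row per impulse).
#'
#' @slot onsets seconds from segment start, sorted ascending.
#' @slot durations seconds.
#' @slot peaks dimensionless peak |amplitude| of each event.
#' @slot spectra matrix of per-impulse normalized power spectra
#'   (rows = impulses, cols = nFft/2 + 1 bins).
#' @slot nFft FFT length used for spectra.
#' @slot sampleRate Hz of the source segment.
#' @slot segmentDuration seconds of the analyzed segment.
#' @export
setClass("ImpulseSet",
  representation(onsets = "numeric", durations = "numeric", peaks = "numeric",
                 spectra = "matrix", nFft = "integer", sampleRate = "numeric",
                 segmentDuration = "numeric"),
  validity = function(object) {
    n <- length(object@onsets)
    if (length(object@durations) != n || length(object@peaks) != n)
      return("onsets, durations, peaks must have equal length")
    if (n > 0 && nrow(object@spectra) != n)
      return("spectra must have one row per impulse")
    if (is.unsorted(object@onsets)) return("onsets must be sorted ascending")
    TRUE
  }
)

setMethod("length", "ImpulseSet", function(x) length(x@onsets))

setMethod("show", "ImpulseSet", function(object) {
  cat(sprintf("ImpulseSet: %d impulses in %.1f s segment @ %g Hz\n",
              length(object@onsets), object@segmentDuration,
              object@sampleRate))
})

#' ImpulseSet accessors
#' @param x an [ImpulseSet-class].
#' @return `impulseOnsets()` onset times (s); `impulseDurations()` durations
#'   (s); `impulseSpectra()` the spectra matrix (rows = impulses);
#'   `segmentDuration()` the analyzed-segment length in seconds.
#' @export
impulseOnsets <- function(x) x@onsets

#' @rdname impulseOnsets
#' @export
impulseDurations <- function(x) x@durations

#' @rdname impulseOnsets
#' @export
impulseSpectra <- function(x) x@spectra

#' @rdname impulseOnsets
#' @export
segmentDuration <- function(x) x@segmentDuration

#' @describeIn impulseOnsets impulses as a data.frame (onset, duration, peak).
#' @param row.names,optional,... passed on conventions of [as.data.frame].
#' @export
setMethod("as.data.frame", "ImpulseSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(onset = x@onsets, duration = x@durations, peak = x@peaks)
  })

# ---------------------------------------------------------------------------
# KernelSpec / AcousticScenario (synthetic-data module)
# ---------------------------------------------------------------------------

#' Specification of a synthetic impulse kernel
#'
#' Parametrizes the brief transients the generator renders: an exponentially
#' damped sinusoid with a raised-cosine onset. Insect feeding/movement
#' impulses are 1-10 ms long, so `duration` is confined to that range.
#'
#' @slot centerFrequency Hz of the carrier.
#' @slot bandwidth Hz; the band within which the kernel's dominant spectral
#'   energy must lie.
#' @slot duration seconds, in [0.001, 0.010].
#' @slot decayRate 1/seconds of the exponential amplitude decay.
#' @slot amplitude dimensionless peak in [0, 1]; 0 renders silence.
#' @export
setClass("KernelSpec",
  representation(centerFrequency = "numeric", bandwidth = "numeric",
                 duration = "numeric", decayRate = "numeric",
                 amplitude = "numeric"),
  validity = function(object) {
    if (object@duration < 0.001 || object@duration > 0.010)
      return("kernel duration must be within 1-10 ms")
    if (object@amplitude < 0 || object@amplitude > 1)
      return("amplitude must be in [0, 1]")
    if (object@centerFrequency <= 0 || object@bandwidth <= 0)
      return("centerFrequency and bandwidth must be positive")
    if (object@decayRate <= 0) return("decayRate must be positive")
    TRUE
  }
)

#' Construct a KernelSpec
#'
#' @param centerFrequency carrier frequency, Hz.
#' @param bandwidth spectral band half... full width around the carrier, Hz.
#' @param duration kernel length in seconds; must lie in [0.001, 0.010].
#' @param decayRate exponential decay constant, 1/s.
#' @param amplitude peak amplitude in [0, 1].
#' @return A [KernelSpec-class] object.
#' @export
kernelSpec <- function(centerFrequency = 4000, bandwidth = 1000,
                       duration = 0.005, decayRate = 1000, amplitude = 0.5) {
  new("KernelSpec", centerFrequency = centerFrequency, bandwidth = bandwidth,
      duration = duration, decayRate = decayRate, amplitude = amplitude)
}

setMethod("show", "KernelSpec", function(object) {
  cat(sprintf(
    "KernelSpec: %.0f Hz (+/- %.0f Hz band), %.1f ms, decay %g/s, amp %.2f\n",
    object@centerFrequency, object@bandwidth, 1000 * object@duration,
    object@decayRate, object@amplitude))
})

#' Scenario for a synthetic ground-truthed recording
#'
#' Defines a recording in which insect sound bursts (trains of >= 3 impulses
#' with intra-burst gaps below 0.2 s) occur as a homogeneous point process,
#' against Gaussian background noise and spectrally distinct distractor
#' transients, so that detection, profile matching and burst grouping can be
#' validated against exact ground truth.
#'
#' @slot duration recording length, seconds (>= 1).
#' @slot sampleRate Hz (default 44100).
#' @slot burstRate bursts per second.
#' @slot impulsesPerBurst integer support of the impulses-per-burst
#'   distribution (uniform over these values); all >= 3.
#' @slot intraBurstGapRange (min, max) gap between impulses in a burst,
#'   seconds; max must stay below the 0.2 s burst-splitting criterion.
#' @slot insectKernel [KernelSpec-class] of insect impulses.
#' @slot noiseFloorRms RMS of the Gaussian background noise.
#' @slot distractorRate isolated non-insect transients per second.
#' @slot distractorKernel [KernelSpec-class] of distractors; must be
#'   spectrally distinct from the insect kernel.
#' @slot rngSeed integer seed; generation is bit-reproducible given it.
#' @export
setClass("AcousticScenario",
  representation(duration = "numeric", sampleRate = "numeric",
                 burstRate = "numeric", impulsesPerBurst = "integer",
                 intraBurstGapRange = "numeric", insectKernel = "KernelSpec",
                 noiseFloorRms = "numeric", distractorRate = "numeric",
                 distractorKernel = "KernelSpec", rngSeed = "integer"),
  validity = function(object) {
    if (object@duration < 1) return("duration must be >= 1 s")
    if (object@burstRate < 0 || object@distractorRate < 0)
      return("rates must be non-negative")
    if (any(object@impulsesPerBurst < 3L))
      return("impulses per burst must be >= 3")
    g <- object@intraBurstGapRange
    if (length(g) != 2L || g[1] <= 0 || g[2] >= 0.2 || g[1] > g[2])
      return("intraBurstGapRange must be within (0, 0.2) with min <= max")
    if (object@noiseFloorRms < 0) return("noiseFloorRms must be >= 0")
    TRUE
  }
)

setMethod("show", "AcousticScenario", function(object) {
  cat(sprintf(
    paste0("AcousticScenario: %.0f s @ %g Hz, %.3g bursts/s ",
           "(%d-%d impulses/burst), noise RMS %.3g, %.3g distractors/s, ",
           "seed %d\n"),
    object@duration, object@sampleRate, object@burstRate,
    min(object@impulsesPerBurst), max(object@impulsesPerBurst),
    object@noiseFloorRms, object@distractorRate, object@rngSeed))
})
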