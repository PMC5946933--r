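# Synthetic ground-truthed data: recordings, hermetic experiments, grain
# counts. These generators define the test bed for the whole pipeline since
# no raw recordings ship with the package.

#' Render an impulse kernel
#'
#' Renders a [KernelSpec-class] as an exponentially damped sinusoid with a
#' raised-cosine onset ramp. The snippet length is `round(duration *
#' sampleRate)` samples (ties to even); the peak absolute amplitude equals
#' `spec@amplitude` exactly, and the dominant spectral energy lies within
#' `centerFrequency` +/- `bandwidth`.
#'
#' @param spec a [KernelSpec-class].
#' @param sampleRate Hz.
#' @return A [Waveform-class] snippet of the kernel.
#' @examples
#' k <- renderKernel(kernelSpec(4000, 1000, 0.005), 44100)
#' length(k)   # 220 samples
#' @export
renderKernel <- function(spec, sampleRate = 44100) {
  validObject(spec)
  n <- durationToSamples(spec@duration, sampleRate)
  t <- (seq_len(n) - 1L) / sampleRate
  if (spec@amplitude == 0) return(waveform(numeric(n), sampleRate))
  # onset ramp: raised cosine over the first quarter (capped at 0.5 ms)
  tOn <- min(5e-4, spec@duration / 4)
  ramp <- ifelse(t < tOn, 0.5 * (1 - cos(pi * t / tOn)), 1)
  x <- ramp * exp(-spec@decayRate * t) * sin(2 * pi * spec@centerFrequency * t)
  peak <- max(abs(x))
  if (peak > 0) x <- x * (spec@amplitude / peak)
  waveform(x, sampleRate)
}

# Normalized spectrum of a rendered kernel (internal; used for the
# spectral-distinctness check and for kernel-derived reference profiles).
kernelSpectrum <- function(spec, sampleRate = 44100, nFft = 256L) {
  w <- renderKernel(spec, sampleRate)
  extractSpectrum(w, onset = 0, duration = duration(w), nFft = nFft)
}

cosineSimilarity <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

#' Construct an AcousticScenario
#'
#' Validates the scenario, including that the insect and distractor kernels
#' are spectrally distinct (cosine similarity of their normalized spectra
#' below 0.9) so that profile rejection is exercised meaningfully.
#'
#' Defaults emulate a laboratory jar recording: insect impulses around 4 kHz
#' in bursts of 3-6 with 30-180 ms gaps, a low-frequency broadband
#' "thud" distractor, and a noise floor placing the impulse peak at a
#' signal-to-noise ratio of 10 (peak amplitude / noise RMS).
#'
#' @param duration seconds (>= 1).
#' @param sampleRate Hz.
#' @param burstRate insect sound bursts per second.
#' @param impulsesPerBurst integer vector; bursts draw their impulse count
#'   uniformly from it (all values >= 3).
#' @param intraBurstGapRange (min, max) seconds between impulses in a burst.
#' @param insectKernel,distractorKernel [KernelSpec-class] objects.
#' @param noiseFloorRms RMS of the Gaussian background.
#' @param distractorRate isolated distractor transients per second.
#' @param rngSeed integer seed.
#' @return An [AcousticScenario-class].
#' @export
acousticScenario <- function(duration = 100, sampleRate = 44100,
                             burstRate = 0.1,
                             impulsesPerBurst = 3:6,
                             intraBurstGapRange = c(0.03, 0.18),
                             insectKernel = kernelSpec(),
                             noiseFloorRms = insectKernel@amplitude / 10,
                             distractorRate = 0.05,
                             distractorKernel = kernelSpec(
                               centerFrequency = 600, bandwidth = 800,
                               duration = 0.008, decayRate = 400,
                               amplitude = insectKernel@amplitude),
                             rngSeed = 1L) {
  sc <- new("AcousticScenario", duration = duration, sampleRate = sampleRate,
            burstRate = burstRate,
            impulsesPerBurst = as.integer(impulsesPerBurst),
            intraBurstGapRange = as.numeric(intraBurstGapRange),
            insectKernel = insectKernel, noiseFloorRms = noiseFloorRms,
            distractorRate = distractorRate,
            distractorKernel = distractorKernel,
            rngSeed = as.integer(rngSeed))
  if (insectKernel@amplitude > 0 && distractorKernel@amplitude > 0) {
    cs <- cosineSimilarity(
      kernelSpectrum(insectKernel, sampleRate)@values,
      kernelSpectrum(distractorKernel, sampleRate)@values)
    if (cs >= 0.9)
      stop(sprintf(paste0("insect and distractor kernels are not spectrally",
                          " distinct (cosine similarity %.3f >= 0.9)"), cs))
  }
  sc
}

#' Generate a ground-truthed synthetic recording
#'
#' Places insect sound bursts by a homogeneous point process at the scenario
#' burst rate. Each burst holds k >= 3 impulses (k uniform over
#' `impulsesPerBurst`) with intra-burst gaps drawn from
#' `intraBurstGapRange`; gaps between consecutive bursts are kept above
#' 0.2 s so generated trains satisfy the burst criterion by construction.
#' Isolated distractor transients and Gaussian noise are added on top.
#' Generation is bit-reproducible given `rngSeed`.
#'
#' @param scenario an [AcousticScenario-class].
#' @return A list with elements:
#'   \describe{
#'     \item{waveform}{the [Waveform-class] recording.}
#'     \item{events}{data.frame of all placed transients:
#'       `onset` (s), `label` ("insect" or "distractor").}
#'     \item{bursts}{data.frame of true burst intervals: `start`, `end` (s),
#'       `impulseCount`.}
#'   }
#' @export
generateRecording <- function(scenario) {
  validObject(scenario)
  withSeed(scenario@rngSeed, {
    fs <- scenario@sampleRate
    nSamp <- durationToSamples(scenario@duration, fs)
    x <- numeric(nSamp)
    kDur <- scenario@insectKernel@duration
    minBurstGap <- 0.201  # > 0.2 s so bursts never merge

    nBursts <- stats::rpois(1L, scenario@burstRate * scenario@duration)
    onsets <- numeric(0)
    labels <- character(0)
    burstDf <- data.frame(start = numeric(0), end = numeric(0),
                          impulseCount = integer(0))
    if (nBursts > 0) {
      counts <- scenario@impulsesPerBurst[
        sample.int(length(scenario@impulsesPerBurst), nBursts, replace = TRUE)]
      gaps <- lapply(counts, function(k)
        stats::runif(k - 1L, scenario@intraBurstGapRange[1],
                     scenario@intraBurstGapRange[2]))
      spans <- vapply(gaps, sum, 0) + kDur
      free <- scenario@duration - sum(spans) - nBursts * minBurstGap
      if (free <= 0)
        stop(paste0("burstRate too high: bursts cannot be separated by ",
                    "> 0.2 s within the recording duration"))
      u <- sort(stats::runif(nBursts, 0, free))
      starts <- u + cumsum(c(0, spans[-nBursts] + minBurstGap))
      burstOnsets <- lapply(seq_len(nBursts), function(i)
        starts[i] + cumsum(c(0, gaps[[i]])))
      onsets <- unlist(burstOnsets)
      labels <- rep("insect", length(onsets))
      burstDf <- data.frame(
        start = starts,
        end = vapply(burstOnsets, max, 0) + kDur,
        impulseCount = counts)
    }

    nDist <- stats::rpois(1L, scenario@distractorRate * scenario@duration)
    if (nDist > 0) {
      dOn <- stats::runif(
        nDist, 0, scenario@duration - scenario@distractorKernel@duration)
      onsets <- c(onsets, dOn)
      labels <- c(labels, rep("distractor", nDist))
    }
    ord <- order(onsets)
    onsets <- onsets[ord]
    labels <- labels[ord]

    insK <- samples(renderKernel(scenario@insectKernel, fs))
    disK <- samples(renderKernel(scenario@distractorKernel, fs))
    for (i in seq_along(onsets)) {
      k <- if (labels[i] == "insect") insK else disK
      s0 <- durationToSamples(onsets[i], fs) + 1L
      idx <- s0:min(s0 + length(k) - 1L, nSamp)
      x[idx] <- x[idx] + k[seq_along(idx)]
    }
    if (scenario@noiseFloorRms > 0)
      x <- x + stats::rnorm(nSamp, 0, scenario@noiseFloorRms)

    list(waveform = waveform(x, fs),
         events = data.frame(onset = onsets, label = labels),
         bursts = burstDf)
  })
}

# ---------------------------------------------------------------------------
# Hermetic experiment generator
# ---------------------------------------------------------------------------

#' Published regression coefficients of activity on oxygen depletion
#'
#' Intercepts and slopes (printed x 1e-3) of the linear models relating
#' insect acoustic activity to oxygen depletion (initial minus residual O2
#' percentage) in hermetically stored wheat infested with adult
#' \emph{Sitophilus oryzae}: `Log10(Rb/Nt + 1)`, `Nb`, and
#' `Log10(Rbimp/Nt + 1)` each regressed on depletion, where `Nt` is the
#' number of insects in the treatment.
#'
#' @return A list with elements `rb`, `nb`, `rbimp`, each
#'   `c(intercept, slope)` on the printed x 1e-3 scale, plus `scale = 1e-3`.
#' @export
defaultActivityCoefficients <- function() {
  list(rb    = c(intercept = 2.26,  slope = -0.156),
       nb    = c(intercept = 4132,  slope = -50.87),
       rbimp = c(intercept = 10.8,  slope = -0.818),
       scale = 1e-3)
}

#' Default observation schedule (days since sealing)
#'
#' Twice daily (morning and evening) for the first 6 days, then twice a week
#' for the rest of a 28-day storage period.
#' @return numeric vector of days.
#' @export
defaultSchedule <- function() {
  c(seq(0.5, 6, by = 0.5), seq(9.5, 27.5, by = 3.5))
}

#' Default treatment layout
#'
#' The six jar treatments: 25, 50 and 100 adults in 500-ml and 1000-ml jars.
#' Air volumes (headspace + intergranular space of the wheat-filled jars) are
#' 260 ml for 500-ml jars and 480 ml for 1000-ml jars.
#' @return data.frame with columns `nInsects`, `jarMl`, `airVolume`.
#' @export
defaultTreatments <- function() {
  data.frame(nInsects = rep(c(25, 50, 100), each = 2),
             jarMl = rep(c(500, 1000), 3),
             airVolume = rep(c(260, 480), 3))
}

#' Design of a synthetic hermetic-storage experiment
#'
#' @param treatments data.frame with columns `nInsects`, `jarMl` and
#'   optionally `airVolume` (defaults: 260 ml for 500-ml jars, 480 ml for
#'   1000-ml jars).
#' @param replicates jars per treatment.
#' @param schedule observation days since sealing.
#' @param o2DecayRatePerInsect decay constant scale `c`, in 1/day per
#'   (insect/ml air): the per-treatment exponential decay rate is
#'   `c * nInsects / airVolume`.
#' @param o2FloorPct asymptotic residual O2 percentage.
#' @param coefficients activity model coefficients as from
#'   [defaultActivityCoefficients()].
#' @param noiseSd named numeric `c(rb=, nb=, rbimp=)`: residual SD of the
#'   activity measures on their model (transformed) scales.
#' @param rngSeed integer seed.
#' @return An object of class `experimentDesign` (a validated list).
#' @export
experimentDesign <- function(treatments = defaultTreatments(),
                             replicates = 3,
                             schedule = defaultSchedule(),
                             o2DecayRatePerInsect = 2.0,
                             o2FloorPct = 0.2,
                             coefficients = defaultActivityCoefficients(),
                             noiseSd = c(rb = 0.25e-3, nb = 0.35,
                                         rbimp = 1.2e-3),
                             rngSeed = 1L) {
  if (o2DecayRatePerInsect < 0)
    stop("o2DecayRatePerInsect must be non-negative")
  if (!all(c("nInsects", "jarMl") %in% names(treatments)))
    stop("treatments must have columns nInsects and jarMl")
  if (is.null(treatments$airVolume))
    treatments$airVolume <- ifelse(treatments$jarMl == 500, 260, 480)
  if (any(treatments$nInsects <= 0)) stop("nInsects must be positive")
  if (o2FloorPct < 0 || o2FloorPct >= 21)
    stop("o2FloorPct must be in [0, 21)")
  if (is.unsorted(schedule) || any(schedule < 0))
    stop("schedule must be ascending non-negative days")
  if (!all(c("rb", "nb", "rbimp") %in% names(noiseSd)))
    stop("noiseSd must name rb, nb and rbimp")
  structure(list(treatments = treatments, replicates = as.integer(replicates),
                 schedule = as.numeric(schedule),
                 o2DecayRatePerInsect = o2DecayRatePerInsect,
                 o2FloorPct = o2FloorPct, coefficients = coefficients,
                 noiseSd = noiseSd, rngSeed = as.integer(rngSeed)),
            class = "experimentDesign")
}

#' Generate a synthetic hermetic-storage experiment table
#'
#' Residual oxygen follows an exponential decline toward a floor,
#' `o2(t) = floor + (21 - floor) * exp(-r t)` with per-treatment rate
#' `r = c * nInsects / airVolume`, so that higher insect density in less air
#' depletes oxygen strictly earlier. Activity measures are generated by
#' inverting the activity-on-depletion models at each timepoint: for the
#' burst rate `Rb` (and `Rbimp`), `Log10(Rb/Nt + 1) = a + b * depletion +
#' noise`, back-transformed and floored at 0; the impulses-per-burst count
#' `Nb` is on the identity scale and is missing whenever no bursts occurred
#' (`Rb = 0`), never 0.
#'
#' @param design an [experimentDesign()].
#' @return data.frame with one row per (treatment, replicate, scheduled day):
#'   `treatmentId`, `nInsects`, `jarMl`, `airVolume`, `replicate`, `day`,
#'   `residualO2`, `rb`, `nb`, `rbimp`.
#' @export
generateExperiment <- function(design) {
  stopifnot(inherits(design, "experimentDesign"))
  tr <- design$treatments
  co <- design$coefficients
  sc <- co$scale
  withSeed(design$rngSeed, {
    rows <- vector("list", nrow(tr) * design$replicates)
    ri <- 0L
    for (i in seq_len(nrow(tr))) {
      rate <- design$o2DecayRatePerInsect * tr$nInsects[i] / tr$airVolume[i]
      tid <- sprintf("%d/%d", tr$nInsects[i], tr$jarMl[i])
      for (rep in seq_len(design$replicates)) {
        o2 <- design$o2FloorPct +
          (21 - design$o2FloorPct) * exp(-rate * design$schedule)
        depl <- 21 - o2
        nT <- tr$nInsects[i]
        yRb <- (co$rb["intercept"] + co$rb["slope"] * depl) * sc +
          stats::rnorm(length(depl), 0, design$noiseSd["rb"])
        rb <- pmax(0, nT * (10^yRb - 1))
        yRbimp <- (co$rbimp["intercept"] + co$rbimp["slope"] * depl) * sc +
          stats::rnorm(length(depl), 0, design$noiseSd["rbimp"])
        rbimp <- pmax(0, nT * (10^yRbimp - 1))
        nb <- (co$nb["intercept"] + co$nb["slope"] * depl) * sc +
          stats::rnorm(length(depl), 0, design$noiseSd["nb"])
        nb <- pmax(0, nb)
        nb[rb == 0] <- NA_real_   # no bursts: impulses per burst undefined
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          treatmentId = tid, nInsects = nT, jarMl = tr$jarMl[i],
          airVolume = tr$airVolume[i], replicate = rep,
          day = design$schedule, residualO2 = o2,
          rb = rb, nb = nb, rbimp = rbimp)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate grain counts realizing a target count-and-weigh weight loss
#'
#' Constructs damaged/undamaged kernel counts and weights such that the
#' count-and-weigh weight-loss formula applied to the output returns
#' `trueLossPct` (within 0.1 percentage points). Damaged kernels lose about
#' 40\% of their weight each (typical of weevil-bored wheat); the damaged
#' count is set accordingly and the exact per-kernel loss back-solved.
#'
#' @param trueLossPct target percentage weight loss in [0, 100).
#' @param nGrains total kernels in the subsample (>= 10).
#' @param rngSeed integer seed (jitters the mean kernel weight).
#' @return list with `wu`, `wd` (grams), `nu`, `nd` (counts).
#' @export
generateGrainCounts <- function(trueLossPct, nGrains = 250, rngSeed = 1L) {
  stopifnotScalar(trueLossPct)
  if (trueLossPct < 0 || trueLossPct >= 100)
    stop("trueLossPct must be in [0, 100)")
  if (nGrains < 10) stop("nGrains must be >= 10")
  withSeed(rngSeed, {
    w0 <- 0.040 * stats::runif(1, 0.9, 1.1)  # mean wheat kernel ~40 mg
    if (trueLossPct == 0) {
      list(wu = nGrains * w0, wd = 0, nu = as.integer(nGrains), nd = 0L)
    } else {
      perKernelLoss <- 0.4
      nd <- max(1L, min(as.integer(round(nGrains * trueLossPct /
                                           (100 * perKernelLoss))),
                        as.integer(nGrains) - 1L))
      # exact per-kernel fractional loss so the formula returns trueLossPct
      delta <- trueLossPct * nGrains / (100 * nd)
      if (delta > 1)
        stop("trueLossPct too high for nGrains: damaged kernels cannot lose ",
             "more than their own weight")
      nu <- as.integer(nGrains) - nd
      list(wu = nu * w0, wd = nd * w0 * (1 - delta), nu = nu, nd = nd)
    }
  })
}
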