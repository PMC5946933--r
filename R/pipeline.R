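# End-to-end convenience: recording -> impulses -> classification -> bursts
# -> activity measures.

#' Analyze a recording segment for insect activity
#'
#' Runs the full detection pipeline on a waveform segment: impulse
#' detection, least-squares spectral classification against the given
#' profiles, burst grouping of the insect-matched impulses, and the three
#' activity measures with the infestation flag.
#'
#' @param w a [Waveform-class] (typically a [selectAnalysisWindow()]
#'   segment).
#' @param profiles list of [SpectralProfile-class] (default the bundled
#'   reference profiles).
#' @param config a [detectionConfig()].
#' @param sseThreshold match criterion (default [defaultSseThreshold()]).
#' @param rbThreshold infestation detection threshold, bursts/s.
#' @return list with `impulses` (classified data.frame), `bursts`
#'   (data.frame), `measures` ([activityMeasures()]), `infested` (logical).
#' @export
analyzeRecording <- function(w, profiles = defaultProfiles(),
                             config = detectionConfig(),
                             sseThreshold = defaultSseThreshold(),
                             rbThreshold = 0.02) {
  imp <- detectImpulses(w, config)
  cls <- classifyImpulses(imp, profiles, sseThreshold)
  bursts <- groupBursts(cls$onset[cls$isInsect])
  meas <- activityMeasures(bursts, segmentDuration(imp))
  list(impulses = cls, bursts = bursts, measures = meas,
       infested = infestationFlag(meas$rb, rbThreshold))
}

#' Analyze a full hermetic-storage experiment table
#'
#' Computes the standard report tables from an experiment table in the
#' layout of [generateExperiment()]: oxygen budgets per treatment x
#' replicate, times to 5\% and 2\% residual O2 with the depletion-rate
#' statistic, the three activity-on-depletion regression fits, and the
#' per-treatment x day summary.
#'
#' @param records experiment data.frame.
#' @return list with data.frames `budgets`, `depletionTimes`, `regressions`,
#'   and `summary`.
#' @export
analyzeExperiment <- function(records) {
  key <- interaction(records$treatmentId, records$replicate, drop = TRUE)
  jars <- split(records, key)
  budgets <- do.call(rbind, lapply(jars, function(d) {
    d <- d[order(d$day), ]
    b <- oxygenBudget(d$airVolume[1L], d$residualO2[1L],
                      d$residualO2[nrow(d)], d$nInsects[1L])
    data.frame(treatmentId = d$treatmentId[1L], replicate = d$replicate[1L],
               initialVolume = b$initialVolume, finalVolume = b$finalVolume,
               consumedPerInsect = b$consumedPerInsect)
  }))
  depletionTimes <- do.call(rbind, lapply(jars, function(d) {
    d <- d[order(d$day), ]
    t5 <- timeToO2Level(d$day, d$residualO2, 5)
    t2 <- timeToO2Level(d$day, d$residualO2, 2)
    data.frame(treatmentId = d$treatmentId[1L], replicate = d$replicate[1L],
               daysTo5pct = t5, daysTo2pct = t2,
               depletionRate = if (is.na(t2) || t2 <= 0) NA_real_ else
                 depletionRate(d$nInsects[1L], t2))
  }))
  regressions <- do.call(rbind, lapply(c("rb", "nb", "rbimp"), function(m) {
    f <- suppressMessages(fitActivityRegression(records, m))
    data.frame(measure = m, transform = f$transform,
               intercept = f$intercept, interceptSe = f$interceptSe,
               slope = f$slope, slopeSe = f$slopeSe, rSquared = f$rSquared,
               fStat = f$fStat, dfNum = f$df[1L], dfDen = f$df[2L],
               pValue = f$pValue, n = f$n)
  }))
  rownames(budgets) <- rownames(depletionTimes) <- rownames(regressions) <- NULL
  list(budgets = budgets, depletionTimes = depletionTimes,
       regressions = regressions, summary = summarizeTreatments(records))
}
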