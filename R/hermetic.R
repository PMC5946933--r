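# Hermetic-storage analysis: oxygen budgets, depletion statistics,
# activity-on-oxygen regressions, and grain-quality metrics.

#' Oxygen budget of a sealed jar
#'
#' Converts oxygen percentages to volumes (`pct/100 * airVolume`; O2 makes
#' up about 21\% of atmospheric air, the default initial percentage) and
#' computes the volume consumed per insect over the storage period.
#' [oxygenBudgetVolumes()] accepts measured initial/final O2 volumes
#' directly, as when working from estimated volume tables.
#'
#' @param airVolume air volume of the sealed jar in ml (headspace +
#'   intergranular space; 260 ml for wheat-filled 500-ml jars, 480 ml for
#'   1000-ml jars).
#' @param initialO2Pct,finalO2Pct O2 percentages at sealing and at opening.
#' @param nInsects number of insects in the jar (> 0).
#' @return list of class `o2Budget`: `initialVolume`, `finalVolume` (ml) and
#'   `consumedPerInsect` (ml/insect). Volume is conserved exactly:
#'   `initialVolume == finalVolume + nInsects * consumedPerInsect`.
#' @examples
#' oxygenBudgetVolumes(95.2, 12.6, 25)$consumedPerInsect  # 3.3 ml
#' @export
oxygenBudget <- function(airVolume, initialO2Pct = 21, finalO2Pct, nInsects) {
  if (airVolume <= 0) stop("airVolume must be positive")
  if (initialO2Pct < 0 || initialO2Pct > 100 || finalO2Pct < 0)
    stop("O2 percentages must be in [0, 100]")
  oxygenBudgetVolumes(initialO2Pct / 100 * airVolume,
                      finalO2Pct / 100 * airVolume, nInsects)
}

#' @rdname oxygenBudget
#' @param initialMl,finalMl measured O2 volumes in ml.
#' @export
oxygenBudgetVolumes <- function(initialMl, finalMl, nInsects) {
  if (nInsects <= 0) stop("nInsects must be positive")
  if (finalMl > initialMl)
    stop(sprintf("final O2 volume (%.3g ml) exceeds initial (%.3g ml)",
                 finalMl, initialMl))
  if (finalMl < 0) stop("O2 volumes must be non-negative")
  structure(list(initialVolume = initialMl, finalVolume = finalMl,
                 consumedPerInsect = (initialMl - finalMl) / nInsects),
            class = "o2Budget")
}

#' @export
print.o2Budget <- function(x, ...) {
  cat(sprintf("O2 budget: %.1f ml -> %.1f ml, %.1f ml consumed per insect\n",
              x$initialVolume, x$finalVolume, x$consumedPerInsect))
  invisible(x)
}

#' Time until residual oxygen first reaches a target level
#'
#' Linear interpolation between the bracketing observations gives the first
#' crossing time of `targetPct`. Returns 0 if the series is already below
#' the target at the first observation, and `NA` if the target is never
#' reached.
#'
#' @param days observation days, strictly ascending.
#' @param o2 residual O2 percentages at those days.
#' @param targetPct target residual O2 percentage (e.g. 5 or 2).
#' @return days (numeric) or `NA`.
#' @export
timeToO2Level <- function(days, o2, targetPct) {
  if (length(days) == 0L) stop("empty series")
  if (length(days) != length(o2)) stop("days and o2 lengths differ")
  if (is.unsorted(days, strictly = TRUE))
    stop("days must be strictly ascending")
  if (o2[1L] < targetPct) return(0)
  if (o2[1L] == targetPct) return(days[1L])
  atOrBelow <- which(o2 <= targetPct)
  if (length(atOrBelow) == 0L) return(NA_real_)
  i <- atOrBelow[1L]
  # interpolate between the last observation above target and this one
  d0 <- days[i - 1L]; d1 <- days[i]
  y0 <- o2[i - 1L]; y1 <- o2[i]
  d0 + (y0 - targetPct) / (y0 - y1) * (d1 - d0)
}

#' Oxygen depletion-rate statistic
#'
#' The population in the treatment jar divided by the number of days until
#' depletion to 2\% O2, reported to 2 decimal places (insects/day).
#'
#' @param nInsects population in the jar.
#' @param daysTo2pct days until residual O2 reached 2\% (> 0), e.g. from
#'   [timeToO2Level()]; `NA` if never reached.
#' @return insects/day, or `NA` when the 2\% level was not reached.
#' @examples
#' depletionRate(100, 5)   # 20
#' depletionRate(50, 12)   # 4.17
#' @export
depletionRate <- function(nInsects, daysTo2pct) {
  if (any(nInsects <= 0)) stop("nInsects must be positive")
  if (any(!is.na(daysTo2pct) & daysTo2pct <= 0))
    stop("daysTo2pct must be positive")
  round(nInsects / daysTo2pct, 2)
}

# ---------------------------------------------------------------------------
# Regressions of activity on oxygen
# ---------------------------------------------------------------------------

# Depletion per record: each replicate's own first (earliest-day) residual
# O2 reading is its initial level, minus the residual at the record's day.
recordDepletion <- function(records) {
  key <- interaction(records$treatmentId, records$replicate, drop = TRUE)
  initial <- vapply(split(records, key), function(d)
    d$residualO2[which.min(d$day)], 0)
  records$depletion <- initial[as.character(key)] - records$residualO2
  records
}

fitToList <- function(fit, transform, extra = list()) {
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic)
  c(list(intercept = unname(stats::coef(fit)[1L]),
         slope = unname(stats::coef(fit)[2L]),
         interceptSe = sm$coefficients[1L, 2L],
         slopeSe = sm$coefficients[2L, 2L],
         rSquared = sm$r.squared,
         fStat = fstat[1L],
         df = c(fstat[2L], fstat[3L]),
         pValue = stats::pf(fstat[1L], fstat[2L], fstat[3L],
                            lower.tail = FALSE),
         n = length(stats::residuals(fit)),
         sigma = sm$sigma,
         transform = transform),
    extra)
}

#' Fit an activity-on-depletion regression across treatments
#'
#' Ordinary least squares of a transformed activity measure on oxygen
#' depletion (initial minus residual O2 percentage, the initial being each
#' replicate's own first reading). The burst rate `Rb` and burst-impulse
#' rate `Rbimp` are normalized per insect and transformed as
#' `Log10(measure/Nt + 1)` before fitting; the impulses-per-burst count `Nb`
#' is already on a narrow natural scale (about 3-6) and is fitted directly.
#' Records with undefined `Nb` (no bursts) are dropped with a message.
#'
#' @param records data.frame in the layout of [generateExperiment()]
#'   (columns `treatmentId`, `nInsects`, `replicate`, `day`, `residualO2`,
#'   and the activity measures).
#' @param measure one of `"rb"`, `"nb"`, `"rbimp"`.
#' @return list of class `regressionFit`: `intercept`, `slope` (with their
#'   standard errors), `rSquared`, `fStat`, `df`, `pValue`, `n`, `sigma`,
#'   `transform`.
#' @export
fitActivityRegression <- function(records, measure = c("rb", "nb", "rbimp")) {
  measure <- match.arg(measure)
  records <- recordDepletion(records)
  if (measure == "nb") {
    y <- records$nb
    transform <- "identity"
    nDropped <- sum(is.na(y))
    if (nDropped > 0)
      message(nDropped, " records with undefined Nb (no bursts) dropped")
  } else {
    y <- log10(records[[measure]] / records$nInsects + 1)
    transform <- "log10p1_per_insect"
  }
  ok <- !is.na(y) & !is.na(records$depletion)
  if (sum(ok) < 3L)
    stop("need at least 3 records with a defined '", measure, "'")
  fit <- stats::lm(y[ok] ~ records$depletion[ok])
  structure(fitToList(fit, transform, list(measure = measure)),
            class = "regressionFit")
}

#' Fit a within-treatment activity regression
#'
#' Simple OLS of an untransformed burst metric on residual O2 (or on
#' depletion) within a single treatment, reporting the coefficient of
#' determination and the error variance `s2` and standard deviation `s`.
#'
#' @param records rows of a single treatment.
#' @param x regressor: `"residualO2"` or `"depletion"`.
#' @param y response: one of `"rb"`, `"nb"`, `"rbimp"`.
#' @return list of class `regressionFit`, with `s2` and `s` in addition to
#'   the usual components.
#' @export
fitTreatmentRegression <- function(records, x = c("residualO2", "depletion"),
                                   y = c("rb", "nb", "rbimp")) {
  x <- match.arg(x)
  y <- match.arg(y)
  if (length(unique(records$treatmentId)) != 1L)
    stop("records must come from a single treatment")
  if (x == "depletion") records <- recordDepletion(records)
  yy <- records[[y]]
  ok <- !is.na(yy) & !is.na(records[[x]])
  if (sum(ok) < 3L) stop("need at least 3 usable records")
  fit <- stats::lm(yy[ok] ~ records[[x]][ok])
  s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  structure(fitToList(fit, "identity",
                      list(measure = y, regressor = x, s2 = s2,
                           s = sqrt(s2))),
            class = "regressionFit")
}

#' @export
print.regressionFit <- function(x, ...) {
  cat(sprintf(
    "Fit (%s, %s): intercept %.4g +/- %.3g, slope %.4g +/- %.3g\n  R2 %.3f, F(%g,%g) = %.3g, p = %.3g, n = %d\n",
    x$measure, x$transform, x$intercept, x$interceptSe, x$slope, x$slopeSe,
    x$rSquared, x$df[1L], x$df[2L], x$fStat, x$pValue, x$n))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Grain quality
# ---------------------------------------------------------------------------

#' Count-and-weigh percentage weight loss
#'
#' `100 * (nd * wu - nu * wd) / (wu * (nu + nd))`, where `wu`/`wd` are the
#' weights and `nu`/`nd` the counts of undamaged and damaged kernels in the
#' subsample. Pathological inputs (damaged kernels heavier per grain than
#' undamaged) give a negative value, returned as computed with a warning.
#'
#' @param wu,wd weights of the undamaged and damaged portions, grams.
#' @param nu,nd kernel counts of the two portions.
#' @return percentage weight loss.
#' @examples
#' weightLoss(wu = 100, wd = 8, nu = 100, nd = 10)  # 1.818
#' @export
weightLoss <- function(wu, wd, nu, nd) {
  if (any(c(wu, wd, nu, nd) < 0)) stop("counts and weights must be non-negative")
  if (nu + nd == 0) stop("no kernels counted (nu + nd = 0)")
  if (wu == 0) stop("wu must be positive")
  loss <- 100 * (nd * wu - nu * wd) / (wu * (nu + nd))
  if (loss < 0)
    warning("negative weight loss: damaged kernels are heavier per grain than undamaged")
  loss
}

#' Germination capacity
#'
#' Percentage of seeds germinating in a fixed assay (four subsamples of 25
#' grains on moist filter paper for 7 days is the standard layout).
#'
#' @param germinatedCounts germinated seeds per dish.
#' @param seedsPerDish seeds placed per dish (default 25).
#' @return list: `percent` (overall), `perDish` (per-dish percentages).
#' @examples
#' germinationCapacity(c(23, 23, 23, 23))$percent  # 92
#' @export
germinationCapacity <- function(germinatedCounts, seedsPerDish = 25) {
  if (any(germinatedCounts < 0)) stop("counts must be non-negative")
  if (any(germinatedCounts > seedsPerDish))
    stop("germinated count exceeds seeds per dish")
  list(percent = 100 * sum(germinatedCounts) /
         (seedsPerDish * length(germinatedCounts)),
       perDish = 100 * germinatedCounts / seedsPerDish)
}

#' Per-treatment, per-day summary table
#'
#' Mean and SEM (sample SD / sqrt(n)) by treatment and day for residual O2
#' and each activity measure. SEM is `NA` for single-replicate cells.
#'
#' @param records data.frame in the layout of [generateExperiment()].
#' @return data.frame: `treatmentId`, `day`, `n`, then `<var>Mean` and
#'   `<var>Sem` for `residualO2`, `rb`, `nb`, `rbimp`.
#' @export
summarizeTreatments <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  vars <- c("residualO2", "rb", "nb", "rbimp")
  key <- interaction(records$treatmentId, records$day, drop = TRUE)
  cells <- split(records, key)
  out <- do.call(rbind, lapply(cells, function(d) {
    row <- data.frame(treatmentId = d$treatmentId[1L], day = d$day[1L],
                      n = nrow(d))
    for (v in vars) {
      x <- d[[v]][!is.na(d[[v]])]
      row[[paste0(v, "Mean")]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0(v, "Sem")]] <-
        if (length(x) >= 2L) stats::sd(x) / sqrt(length(x)) else NA_real_
    }
    row
  }))
  out <- out[order(out$treatmentId, out$day), ]
  rownames(out) <- NULL
  out
}
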