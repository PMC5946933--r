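# Burst grouping and the three activity measures (Rb, Nb, Rbimp), plus the
# infestation-likelihood threshold and activity-cessation location.

#' Group insect impulse onsets into sound bursts
#'
#' A burst is a maximal run of impulses whose consecutive gaps are strictly
#' below `maxGap` (200 ms) containing at least `minCount` (3) impulses; a
#' gap of exactly `maxGap` splits. Shorter runs are discarded.
#'
#' @param onsets insect-matched impulse onset times in seconds, sorted
#'   ascending.
#' @param maxGap strict gap criterion in seconds (default 0.2).
#' @param minCount minimum impulses per burst (default 3).
#' @return data.frame with one row per burst: `start`, `end` (first and last
#'   impulse onset, s), `impulseCount`.
#' @examples
#' groupBursts(c(0.0, 0.10, 0.25, 1.00, 1.10, 1.15, 1.30))
#' @export
groupBursts <- function(onsets, maxGap = 0.2, minCount = 3) {
  if (is.unsorted(onsets)) stop("onsets must be sorted ascending")
  if (length(onsets) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      impulseCount = integer(0)))
  runId <- cumsum(c(TRUE, diff(onsets) >= maxGap))
  starts <- tapply(onsets, runId, min)
  ends <- tapply(onsets, runId, max)
  counts <- tapply(onsets, runId, length)
  keep <- counts >= minCount
  data.frame(start = as.numeric(starts[keep]), end = as.numeric(ends[keep]),
             impulseCount = as.integer(counts[keep]))
}

#' Activity measures of an analyzed segment
#'
#' The three acoustic measures of insect activity: the burst rate `Rb`
#' (bursts/s), the mean impulses per burst `Nb`, and the burst-impulse rate
#' `Rbimp` (impulses within bursts, per second). When no bursts occurred,
#' `Rb` and `Rbimp` are 0 and `Nb` is `NA` (undefined, never 0).
#'
#' @param bursts data.frame from [groupBursts()].
#' @param duration analyzed-segment length in seconds (> 0).
#' @return list of class `activityMeasures` with `rb`, `nb`, `rbimp`,
#'   `duration`, `nBursts`.
#' @export
activityMeasures <- function(bursts, duration) {
  stopifnotScalar(duration)
  if (duration <= 0) stop("duration must be positive")
  n <- nrow(bursts)
  totImp <- sum(bursts$impulseCount)
  structure(list(rb = n / duration,
                 nb = if (n >= 1L) totImp / n else NA_real_,
                 rbimp = totImp / duration,
                 duration = duration, nBursts = n),
            class = "activityMeasures")
}

#' @export
print.activityMeasures <- function(x, ...) {
  cat(sprintf(
    "Activity: Rb %.4g bursts/s, Nb %s impulses/burst, Rbimp %.4g/s (%d bursts in %.1f s)\n",
    x$rb, if (is.na(x$nb)) "NA" else sprintf("%.3g", x$nb), x$rbimp,
    x$nBursts, x$duration))
  invisible(x)
}

#' Infestation-likelihood flag
#'
#' A minimum rate of 0.02 bursts per second is the detection threshold below
#' which a sample is considered to have a low likelihood of infestation. The
#' comparison is inclusive: a burst rate exactly at the threshold flags as
#' infested, since the threshold is a minimum detectable rate.
#'
#' @param rb burst rate, bursts/s (>= 0).
#' @param threshold detection threshold (default 0.02 bursts/s).
#' @return logical.
#' @export
infestationFlag <- function(rb, threshold = 0.02) {
  if (any(rb < 0)) stop("burst rate must be non-negative")
  rb >= threshold
}

#' Time of sustained activity cessation (quiescence)
#'
#' Returns the first observed day at which the burst rate is below the
#' detection threshold and remains below it at all later observed days. The
#' crossing must be sustained because day-to-day rates are non-monotone
#' (activity can reappear after a silent observation). `NA` if the rate
#' never falls below threshold for good.
#'
#' @param days observation days, ascending.
#' @param rb burst rates at those days.
#' @param threshold detection threshold (default 0.02 bursts/s).
#' @return day (numeric) or `NA`.
#' @examples
#' timeToQuiescence(1:5, c(0.37, 0.05, 0.02, 0, 0))  # 4
#' @export
timeToQuiescence <- function(days, rb, threshold = 0.02) {
  if (length(days) == 0L) stop("empty series")
  if (length(days) != length(rb)) stop("days and rb lengths differ")
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly ascending")
  below <- rb < threshold
  sustained <- rev(cumprod(rev(below))) == 1
  if (!any(sustained)) return(NA_real_)
  days[which(sustained)[1L]]
}
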