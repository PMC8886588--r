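# Non-parametric period estimation by folding, circular statistics of
# sleep timing, and light-exposure summaries.

#' Dominant-period estimation by data folding
#'
#' Folds a recording channel at a grid of candidate periodicities and
#' phase-bins the epochs into bins of width \code{step} modulo each
#' candidate period.  The residual variance at a candidate is the pooled
#' within-bin sum of squares divided by the total sum of squares (a
#' unit-free fraction in \code{[0, 1]}, invariant under affine transforms
#' of the signal); the candidate with the smallest residual variance is
#' the dominant period.  This waveform-agnostic estimator makes no
#' assumption about rhythm shape.
#'
#' Partial phase bins at the series end enter with their actual
#' occupancy; bins with fewer than two samples contribute zero within-bin
#' variance and are counted in the \code{sparseBins} diagnostic.
#'
#' @param series an [EpochSeries-class].
#' @param channel \code{"activity"} or \code{"lux"}.
#' @param periodRange numeric length-2, candidate period range in hours.
#'   The default 20-28 h covers free-running periods well beyond the
#'   physiological range of fitted intrinsic periods.
#' @param step grid step in seconds; must equal the epoch length (the
#'   resolution of the data), which is the default.
#' @return a [PeriodScan-class].
#' @section Errors: a constant signal raises a degenerate-signal error; a
#'   period range outside \code{(2 * step, span / 3)} a range error.
#' @examples
#' es <- epochSeries("2024-01-01", activity = rep(rep(c(0, 100),
#'                   each = 360), 42), lux = rep(0, 30240))
#' scan <- foldPeriodScan(es)
#' scan@dominantPeriod  # 24
#' @export
foldPeriodScan <- function(series, channel = c("activity", "lux"),
                           periodRange = c(20, 28),
                           step = epochLength(series)) {
  channel <- match.arg(channel)
  stepH <- step / 3600
  x <- if (channel == "activity") series@activity else series@lux
  ok <- !series@missing & !is.na(x)
  x <- x[ok]
  tH <- (which(ok) - 1) * (series@epochLength / 3600)
  spanH <- length(series@activity) * series@epochLength / 3600
  if (periodRange[1] <= 2 * stepH || periodRange[2] > spanH / 3)
    clRangeError(sprintf(
      "period range must lie within (%.3f, %.3f) h for this recording",
      2 * stepH, spanH / 3))
  totSS <- sum((x - mean(x))^2)
  if (totSS <= 0) clDegenerateError("constant signal: variance is zero")
  candidates <- seq(periodRange[1], periodRange[2], by = stepH)
  nSparse <- integer(length(candidates))
  rv <- vapply(seq_along(candidates), function(i) {
    P <- candidates[i]
    bin <- floor((tH %% P) / stepH)
    s1 <- rowsum(x, bin)
    s2 <- rowsum(x^2, bin)
    nb <- rowsum(rep(1, length(x)), bin)
    withinSS <- sum(s2 - s1^2 / nb)
    rv <- withinSS / totSS
    max(0, min(1, rv))
  }, numeric(1))
  best <- which.min(rv)  # ties resolve to the smallest candidate
  P <- candidates[best]
  bin <- floor((tH %% P) / stepH)
  sparse <- sum(tabulate(bin + 1) < 2)
  new("PeriodScan", candidatePeriods = candidates, residualVariance = rv,
      dominantPeriod = P, depth = rv[best] / median(rv),
      sparseBins = as.integer(sparse))
}

setMethod("show", "PeriodScan", function(object) {
  cat(sprintf(
    "PeriodScan: %d candidates in [%.2f, %.2f] h\n",
    length(object@candidatePeriods), min(object@candidatePeriods),
    max(object@candidatePeriods)))
  cat(sprintf("  dominant period %.4f h (residual variance %.3f, depth %.3f)\n",
              object@dominantPeriod,
              object@residualVariance[which.min(object@residualVariance)],
              object@depth))
})

#' Circular statistics of a set of clock times
#'
#' Maps each clock time t to the angle 2 pi t / 24, averages the unit
#' vectors, and maps the mean direction back to a clock time.  The
#' circular SD is \code{(24 / 2 pi) * sqrt(-2 log R)} where R is the mean
#' resultant length.  When R is numerically zero (times spread uniformly
#' around the clock) the mean is undefined: the result is flagged, not an
#' error.
#'
#' @param times clock times: numeric hours, or POSIXct (converted to
#'   hours since midnight).
#' @return a [CircularTimeStats-class].
#' @examples
#' circularTimeStats(c(23.5, 0.5))@meanTime  # 0, not 12
#' @export
circularTimeStats <- function(times) {
  if (inherits(times, "POSIXct")) times <- clockHours(times)
  times <- as.numeric(times)
  if (length(times) < 2)
    clInsufficientError("need at least two times")
  th <- times / 24 * 2 * pi
  s <- mean(sin(th)); c <- mean(cos(th))
  R <- sqrt(s^2 + c^2)
  flags <- character(0)
  if (R < 1e-12) {
    mt <- NA_real_
    csd <- Inf
    flags <- "undefined_mean"
  } else {
    mt <- (atan2(s, c) / (2 * pi) * 24) %% 24
    if (24 - mt < 1e-9) mt <- 0
    csd <- if (R >= 1 - 1e-12) 0 else (24 / (2 * pi)) * sqrt(-2 * log(R))
  }
  new("CircularTimeStats", meanTime = mt, resultantLength = min(R, 1),
      circularVariance = 1 - min(R, 1), circularSD = csd,
      n = length(times), flags = flags)
}

setMethod("show", "CircularTimeStats", function(object) {
  if (length(object@flags) && "undefined_mean" %in% object@flags) {
    cat(sprintf("CircularTimeStats: n = %d, mean undefined (R = 0)\n",
                object@n))
  } else {
    cat(sprintf(
      "CircularTimeStats: n = %d, mean %02d:%02d, R %.3f, circular SD %.2f h\n",
      object@n, floor(object@meanTime),
      round((object@meanTime %% 1) * 60), object@resultantLength,
      object@circularSD))
  }
})

#' Per-participant summary of sleep timing
#'
#' Linear mean and SD of episode durations, and circular statistics of
#' sleep onset, offset and mid-sleep clock times (mid-sleep is the
#' midpoint of each episode).  Circular statistics are used because
#' irregular sleepers can place these times anywhere around the clock.
#'
#' @param episodes a [SleepEpisodes-class]; at least 7 episodes are
#'   expected for a stable summary (fewer than 2 is an error).
#' @return a list with elements \code{durationMean}, \code{durationSD}
#'   (hours), and [CircularTimeStats-class] objects \code{onset},
#'   \code{offset}, \code{midSleep}, plus \code{n}.
#' @export
sleepTimingSummary <- function(episodes) {
  n <- nEpisodes(episodes)
  if (n < 2)
    clInsufficientError("need at least two sleep episodes")
  if (n < 7)
    warning("fewer than 7 episodes: summary will be unstable")
  tab <- episodeTable(episodes)
  list(durationMean = mean(tab$duration), durationSD = sd(tab$duration),
       onset = circularTimeStats(tab$onset),
       offset = circularTimeStats(tab$offset),
       midSleep = circularTimeStats(tab$midSleep),
       n = n)
}

#' Light-exposure metrics of a recording
#'
#' For each complete calendar day of the recording, computes the hours
#' with illuminance strictly above \code{brightLux}, the mean lux, and
#' the mean \code{log(lux + 1)}; reports the median across days of each.
#' Missing epochs are excluded (not zero-filled); a day counts as
#' complete when at least 90 percent of its epochs are non-missing.
#'
#' @param series an [EpochSeries-class] covering at least 7 complete
#'   days.
#' @param brightLux bright-light threshold in lux (strict inequality;
#'   default 500).
#' @return a [LightMetrics-class].
#' @examples
#' es <- epochSeries("2024-01-01", activity = rep(0, 720 * 10),
#'                   lux = rep(c(rep(1000, 360), rep(0, 360)), 10))
#' lightMetrics(es)@medianBrightHours  # 12
#' @export
lightMetrics <- function(series, brightLux = 500) {
  epH <- series@epochLength / 3600
  n <- length(series@lux)
  # calendar day index of each epoch relative to the first midnight
  t0 <- clockHours(series@start)
  day <- floor((t0 + (seq_len(n) - 1) * epH) / 24)
  ok <- !series@missing & !is.na(series@lux)
  if (!any(ok)) clInsufficientError("no usable days: all epochs masked")
  perDay <- 24 / epH
  nOk <- rowsum(as.numeric(ok), day)[, 1]
  use <- as.numeric(names(nOk)[nOk >= 0.9 * perDay])
  if (length(use) < 1) clInsufficientError("no complete days in recording")
  if (length(use) < 7)
    warning("fewer than 7 complete days: light summary will be unstable")
  sel <- ok & day %in% use
  dayIdx <- day[sel]; lx <- series@lux[sel]
  bright <- rowsum(as.numeric(lx > brightLux), dayIdx)[, 1] * epH
  meanLux <- rowsum(lx, dayIdx)[, 1] / tabulate(factor(dayIdx))
  meanLog <- rowsum(log(lx + 1), dayIdx)[, 1] / tabulate(factor(dayIdx))
  new("LightMetrics",
      medianBrightHours = median(bright),
      medianDailyLux = median(meanLux),
      medianDailyLogLux = median(meanLog),
      brightThreshold = brightLux, nDays = length(use))
}

setMethod("show", "LightMetrics", function(object) {
  cat(sprintf(
    "LightMetrics over %d days: bright (>%g lux) %.2f h/day, mean %.1f lux, mean log-lux %.2f\n",
    object@nDays, object@brightThreshold, object@medianBrightHours,
    object@medianDailyLux, object@medianDailyLogLux))
})
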