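# Parametric available-light profiles, entrainment classification over
# (daytime, evening) intensity grids, and target-wake-time intervention
# search.

#' Construct an available-light profile
#'
#' A smooth 24-h periodic curve describing the light a person could be
#' exposed to if awake: a raised-cosine bump that climbs from the
#' evening/night floor \code{LEve} at \code{riseTime}, peaks at
#' \code{LDay} at \code{peakTime}, and returns to \code{LEve} by
#' \code{declineTime}.
#'
#' @param LDay peak daytime illuminance (lux); must be \code{>= LEve}.
#' @param LEve evening/night illuminance (lux); \code{>= 0}.
#' @param riseTime,peakTime,declineTime shape clock hours (defaults
#'   07:00, 13:00, 21:00).
#' @return an [AvailableLightProfile-class].
#' @examples
#' prof <- availableLightProfile(795, 7)
#' profileIlluminance(prof, c(3, 13, 23))  # 7, 795, 7
#' @export
availableLightProfile <- function(LDay, LEve, riseTime = 7, peakTime = 13,
                                  declineTime = 21) {
  if (LDay < LEve)
    clArgumentError("LDay must be >= LEve")
  new("AvailableLightProfile", LDay = as.numeric(LDay),
      LEve = as.numeric(LEve), riseTime = riseTime, peakTime = peakTime,
      declineTime = declineTime)
}

#' Evaluate an available-light profile at clock times
#'
#' @param profile an [AvailableLightProfile-class].
#' @param clockTime numeric clock hours (taken modulo 24).
#' @return illuminance in lux.
#' @export
profileIlluminance <- function(profile, clockTime) {
  ck <- clockTime %% 24
  L <- rep(profile@LEve, length(ck))
  up <- ck > profile@riseTime & ck <= profile@peakTime
  dn <- ck > profile@peakTime & ck < profile@declineTime
  amp <- profile@LDay - profile@LEve
  L[up] <- profile@LEve + amp * 0.5 *
    (1 - cos(pi * (ck[up] - profile@riseTime) /
               (profile@peakTime - profile@riseTime)))
  L[dn] <- profile@LEve + amp * 0.5 *
    (1 + cos(pi * (ck[dn] - profile@peakTime) /
               (profile@declineTime - profile@peakTime)))
  L
}

setMethod("show", "AvailableLightProfile", function(object) {
  cat(sprintf(
    "AvailableLightProfile: day peak %g lux at %02.0f:00, evening %g lux (rise %02.0f:00, decline %02.0f:00)\n",
    object@LDay, object@peakTime, object@LEve, object@riseTime,
    object@declineTime))
})

#' Classify entrainment under an available-light profile
#'
#' Simulates the model in self-selected mode under \code{profile} and
#' classifies the individual as entrained when the sleep-onset period
#' over the final post-transient window is within \code{tol} of 24 h.
#' For entrained individuals the circular mean sleep offset over that
#' window is reported; for non-entrained individuals the offset is
#' meaningless (it drifts) and is \code{NA}.
#'
#' @param params a [ModelParams-class].
#' @param profile an [AvailableLightProfile-class].
#' @param days simulation length (days); the final 28 days are the
#'   classification window and everything before them is transient, so
#'   \code{days} must be at least 38.  The default 70 leaves a 42-day
#'   transient, long enough for slow phase convergence near the
#'   entrainment boundary.
#' @param tol entrainment tolerance on the onset period in hours
#'   (default 2 minutes).
#' @return list with elements \code{entrained} (logical),
#'   \code{onsetPeriod} (h), \code{meanOffset} (clock h or NA),
#'   \code{failed} (logical).
#' @export
classifyEntrainment <- function(params, profile, days = 70, tol = 2 / 60) {
  if (days < 38)
    clArgumentError("days must be >= 38 (28-day window + 10-day transient)")
  transient <- days - 28
  out <- tryCatch({
    sim <- simulateModel(params, profile, days = days,
                         transientDays = transient)
    ep <- sim@episodes
    post <- ep[ep$onset >= transient * 24, , drop = FALSE]
    if (nrow(post) < 7) {
      list(entrained = FALSE, onsetPeriod = NA_real_,
           meanOffset = NA_real_, failed = TRUE)
    } else {
      per <- .onsetPeriodHours(post$onset)
      entr <- is.finite(per) && abs(per - 24) <= tol
      mo <- if (entr) circMeanHours(post$offset %% 24) else NA_real_
      list(entrained = entr, onsetPeriod = per, meanOffset = mo,
           failed = FALSE)
    }
  }, error = function(e) {
    list(entrained = FALSE, onsetPeriod = NA_real_, meanOffset = NA_real_,
         failed = TRUE)
  })
  out
}

#' Map entrainment over a grid of light intensities
#'
#' Runs [classifyEntrainment()] at every combination of daytime peak and
#' evening illuminance.  The entrained/non-entrained interface of the
#' resulting map is the individual's entrainment boundary: light of
#' insufficient intensity during the day, or of too high an intensity in
#' the evening, places the individual outside the entrained region.
#'
#' @param params a [ModelParams-class].
#' @param LDayGrid,LEveGrid monotone increasing lux grids.  Defaults are
#'   log-spaced, 67 points over \code{[10, 2000]} lux for the day and 67
#'   over \code{[0.5, 100]} lux for the evening (about 4500
#'   simulations); pass shorter grids for quick maps.
#' @param days,tol passed to [classifyEntrainment()].
#' @param shape optional profile shape times \code{c(rise, peak,
#'   decline)}.
#' @return an [EntrainmentMap-class]; individual simulation failures are
#'   recorded in the \code{failed} column and the map is still returned.
#' @export
entrainmentMap <- function(params,
                           LDayGrid = exp(seq(log(10), log(2000),
                                              length.out = 67)),
                           LEveGrid = exp(seq(log(0.5), log(100),
                                              length.out = 67)),
                           days = 70, tol = 2 / 60,
                           shape = c(7, 13, 21)) {
  if (is.unsorted(LDayGrid, strictly = TRUE) ||
      is.unsorted(LEveGrid, strictly = TRUE))
    clArgumentError("grids must be strictly increasing")
  g <- expand.grid(LDay = LDayGrid, LEve = LEveGrid)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    if (g$LDay[i] < g$LEve[i])
      return(data.frame(LDay = g$LDay[i], LEve = g$LEve[i],
                        entrained = FALSE, onsetPeriod = NA_real_,
                        meanOffset = NA_real_, failed = TRUE))
    prof <- availableLightProfile(g$LDay[i], g$LEve[i], shape[1], shape[2],
                                  shape[3])
    cl <- classifyEntrainment(params, prof, days = days, tol = tol)
    data.frame(LDay = g$LDay[i], LEve = g$LEve[i],
               entrained = cl$entrained, onsetPeriod = cl$onsetPeriod,
               meanOffset = cl$meanOffset, failed = cl$failed)
  })
  new("EntrainmentMap", grid = do.call(rbind, rows),
      tauC = tauC(params), deltaD = deltaD(params), tol = tol)
}

setMethod("show", "EntrainmentMap", function(object) {
  g <- object@grid
  cat(sprintf(
    "EntrainmentMap (tauC %.2f, deltaD %+.2f): %d points, %d entrained, %d failed\n",
    object@tauC, object@deltaD, nrow(g), sum(g$entrained), sum(g$failed)))
})

#' Design available-light interventions for a target wake time
#'
#' Returns every entrained grid point of an entrainment map whose mean
#' sleep offset is within \code{offsetsTol} of the target wake time,
#' sorted by total light change from a reference profile (so the least
#' disruptive interventions come first).  Because the same sleep timing
#' can be reached by raising daytime light, lowering evening light, or a
#' mixture, the returned set typically contains qualitatively different
#' profiles; the choice among them can follow personal preference.
#'
#' @param map an [EntrainmentMap-class] (or NULL, in which case
#'   \code{params} and grids must be supplied to compute one).
#' @param targetOffset target wake time as a clock hour (e.g. 8.5 for
#'   08:30).
#' @param offsetsTol tolerance around the target (h, default 0.25).
#' @param reference numeric \code{c(LDay, LEve)} of the habitual profile
#'   used to rank candidates by total light change (default the dim
#'   environment \code{c(160, 30)}).
#' @param params,... used to compute a map when \code{map} is NULL
#'   (passed to [entrainmentMap()]).
#' @return data.frame of candidate \code{(LDay, LEve)} profiles with
#'   their mean offsets, sorted by light change; zero rows (with
#'   attribute \code{noSolution = TRUE}) when the target is infeasible
#'   for this physiology.
#' @export
designIntervention <- function(map = NULL, targetOffset, offsetsTol = 0.25,
                               reference = c(160, 30), params = NULL, ...) {
  if (is.null(map)) {
    if (is.null(params))
      clArgumentError("supply either a map or params")
    map <- entrainmentMap(params, ...)
  }
  g <- map@grid
  ok <- g$entrained & !g$failed & !is.na(g$meanOffset) &
    circDistHours(g$meanOffset, targetOffset) <= offsetsTol
  out <- g[ok, c("LDay", "LEve", "onsetPeriod", "meanOffset")]
  if (nrow(out)) {
    out$lightChange <- abs(out$LDay - reference[1]) +
      abs(out$LEve - reference[2])
    out <- out[order(out$lightChange), ]
    rownames(out) <- NULL
  } else {
    attr(out, "noSolution") <- TRUE
  }
  out
}
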