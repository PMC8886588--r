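# Per-individual estimation of (tauC, deltaD) from observed light and
# sleep timing, and validation of the fitted model against melatonin
# acrophase.

# objective pieces for one parameter pair: squared circular distance
# between model and observed mean mid-sleep plus squared difference in
# mean duration (hour scale, equal weights), with the model's onset
# period kept as a basin-disambiguation diagnostic
.fitEval <- function(tauCv, deltaDv, recording, obsMid, obsDur,
                     transientDays, cache) {
  key <- sprintf("%.4f_%.4f", tauCv, deltaDv)
  if (!is.null(cache[[key]])) return(cache[[key]])
  out <- tryCatch({
    sim <- simulateModel(modelParams(tauC = tauCv, deltaD = deltaDv),
                         recording, transientDays = transientDays)
    ep <- sim@episodes
    post <- ep[ep$onset >= transientDays * 24, , drop = FALSE]
    if (nrow(post) < 2) {
      list(J = 1e3, per = NA_real_)
    } else {
      mid <- circMeanHours(((post$onset + post$offset) / 2) %% 24)
      dur <- mean(post$offset - post$onset)
      per <- if (nrow(post) >= 7) .onsetPeriodHours(post$onset) else
        NA_real_
      list(J = circDiffHours(mid, obsMid)^2 + (dur - obsDur)^2,
           per = per)
    }
  }, error = function(e) list(J = 1e3, per = NA_real_))
  cache[[key]] <- out
  out
}

#' Fit the two individual parameters from light and sleep timing
#'
#' Estimates the intrinsic circadian period \code{tauC} and the
#' wake-drive deviation \code{deltaD} of one participant by matching the
#' model's mean sleep timing and duration to the observed ones.  The
#' model is driven by the participant's own recorded light (imposed
#' mode, masked to zero during model sleep), so the estimate separates
#' what the light environment explains from what requires individual
#' physiology.  The objective is the squared circular distance between
#' model and observed circular-mean mid-sleep plus the squared
#' difference in mean sleep duration (both in hours, equal weights),
#' evaluated over the same post-transient window for model and data.
#'
#' Optimization is deterministic: a coarse parameter grid is scanned,
#' coarse points close to the grid optimum are clustered into basins
#' along \code{tauC}, and each basin is polished by a finer local grid
#' plus Nelder-Mead.  Because the circular mean of a drifting (non-24-h)
#' record aliases --- very different intrinsic periods can place the mean
#' mid-sleep at the same clock position --- near-optimal basins are
#' disambiguated by a quantity the mean does not carry: the drift rate.
#' Among basins whose objective lies within \code{basinTol} of the best,
#' the fit selects the one whose simulated sleep-onset period is closest
#' to the observed onset period.  More than one near-optimal basin also
#' raises the \code{"multimodal"} flag, and estimates on the search-box
#' boundary the \code{"boundary"} flag.
#'
#' @param record a [ParticipantRecord-class] with at least 14 diary
#'   episodes whose span the recording covers.
#' @param searchBox numeric \code{c(tauC lo, tauC hi, deltaD lo, deltaD
#'   hi)}; default \code{c(23.5, 25.5, -5, 3)}.
#' @param transientDays days of record used to absorb the initial-state
#'   transient and excluded from the matched statistics (default 14).
#' @param acrophaseOffset fixed CWPM-to-acrophase offset (h) used for
#'   the predicted acrophase times; see [predictAcrophase()].
#' @param coarseStep,refineStep grid steps \code{c(tauC, deltaD)} of the
#'   two grid stages.
#' @param basinTol objective tolerance defining near-optimal basins.
#' @return a [FitResult-class].
#' @export
fitParticipant <- function(record, searchBox = c(23.5, 25.5, -5, 3),
                           transientDays = 14, acrophaseOffset = 0.5,
                           coarseStep = c(0.25, 1.0),
                           refineStep = c(0.1, 0.25), basinTol = 0.25) {
  recording <- record@recording
  epTab <- episodeTable(record@episodes)
  if (nrow(epTab) < 14)
    clInsufficientError("need at least 14 diary episodes to fit")
  # hour axis anchored at the first midnight covered by the recording
  ck <- clockHours(recording@start)
  origin <- recording@start +
    (if (ck < 1e-9) 0 else (24 - ck) * 3600)
  onH <- hoursSince(epTab$onset, origin)
  post <- onH >= transientDays * 24
  if (sum(post) < 7)
    clInsufficientError("need at least 7 episodes after the transient window")
  obsMid <- circMeanHours(clockHours(epTab$midSleep[post]))
  obsDur <- mean(epTab$duration[post])
  obsPer <- .onsetPeriodHours(onH[post])
  lo <- searchBox[c(1, 3)]; hi <- searchBox[c(2, 4)]

  cache <- new.env(parent = emptyenv())
  ev <- function(tc, dd) .fitEval(tc, dd, recording, obsMid, obsDur,
                                  transientDays, cache)
  Jof <- function(tc, dd) ev(tc, dd)$J

  tcGrid <- seq(lo[1], hi[1], by = coarseStep[1])
  ddGrid <- seq(lo[2], hi[2], by = coarseStep[2])
  coarse <- expand.grid(tauC = tcGrid, deltaD = ddGrid)
  coarse$J <- mapply(Jof, coarse$tauC, coarse$deltaD)
  coarseMin <- min(coarse$J)

  # cluster promising coarse points into basins along tauC
  cand <- coarse[coarse$J <= coarseMin + max(1.0, basinTol), , drop = FALSE]
  tcs <- sort(unique(cand$tauC))
  gaps <- which(diff(tcs) > coarseStep[1] * 1.5)
  basinId <- findInterval(cand$tauC, tcs[gaps] + 1e-9) + 1
  basins <- lapply(split(cand, basinId), function(d) d[which.min(d$J), ])

  polish <- function(start) {
    tcFine <- seq(max(lo[1], start$tauC - coarseStep[1]),
                  min(hi[1], start$tauC + coarseStep[1]),
                  by = refineStep[1])
    ddFine <- seq(max(lo[2], start$deltaD - 0.5 * coarseStep[2]),
                  min(hi[2], start$deltaD + 0.5 * coarseStep[2]),
                  by = refineStep[2])
    fine <- expand.grid(tauC = tcFine, deltaD = ddFine)
    fine$J <- mapply(Jof, fine$tauC, fine$deltaD)
    bf <- which.min(fine$J)
    pen <- function(par) {
      if (par[1] < lo[1] || par[1] > hi[1] || par[2] < lo[2] ||
          par[2] > hi[2])
        return(1e4 + sum(pmax(0, lo - par)^2 + pmax(0, par - hi)^2))
      Jof(par[1], par[2])
    }
    opt <- optim(c(fine$tauC[bf], fine$deltaD[bf]), pen,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-3, maxit = 40))
    if (opt$value <= fine$J[bf]) {
      list(tauC = opt$par[1], deltaD = opt$par[2], J = opt$value, conv = 0)
    } else {
      list(tauC = fine$tauC[bf], deltaD = fine$deltaD[bf],
           J = fine$J[bf], conv = opt$convergence)
    }
  }
  polished <- lapply(basins, polish)
  Js <- vapply(polished, `[[`, numeric(1), "J")
  bestJ <- min(Js)
  near <- which(Js <= bestJ + max(basinTol, 0.5 * bestJ))
  # among near-optimal basins, prefer the one reproducing the observed
  # drift rate
  perMiss <- vapply(near, function(i) {
    p <- polished[[i]]
    per <- ev(p$tauC, p$deltaD)$per
    if (is.na(per)) Inf else abs(per - obsPer)
  }, numeric(1))
  sel <- polished[[near[which.min(perMiss)]]]

  flags <- character(0)
  if (sel$conv != 0) flags <- c(flags, "no_convergence")
  if (length(near) > 1) flags <- c(flags, "multimodal")
  if (sel$tauC - lo[1] < 0.02 || hi[1] - sel$tauC < 0.02 ||
      sel$deltaD - lo[2] < 0.05 || hi[2] - sel$deltaD < 0.05)
    flags <- c(flags, "boundary")

  sim <- simulateModel(modelParams(tauC = sel$tauC, deltaD = sel$deltaD),
                       recording, transientDays = transientDays)
  mep <- sim@episodes
  mpost <- mep[mep$onset >= transientDays * 24, , drop = FALSE]
  predMid <- circMeanHours(((mpost$onset + mpost$offset) / 2) %% 24)
  predDur <- mean(mpost$offset - mpost$onset)
  predAcro <- predictAcrophase(sim, offset = acrophaseOffset)

  basinTab <- do.call(rbind, lapply(polished, function(p)
    data.frame(tauC = p$tauC, deltaD = p$deltaD, J = p$J)))

  new("FitResult", tauCHat = sel$tauC, deltaDHat = sel$deltaD,
      objective = sel$J, predictedMidSleep = predMid,
      predictedDuration = predDur, observedMidSleep = obsMid,
      observedDuration = obsDur, predictedAcrophase = predAcro,
      searchBox = searchBox,
      convergence = list(coarse = coarse, basins = basinTab,
                         nearOptimalBasins = basinTab[near, , drop = FALSE],
                         observedOnsetPeriod = obsPer),
      flags = flags)
}

setMethod("show", "FitResult", function(object) {
  hm <- sprintf("%d:%02d", floor(object@tauCHat),
                round((object@tauCHat %% 1) * 60))
  cat(sprintf(
    "FitResult: tauC %.4f h (%s h:m), deltaD %+.3f, objective %.4g\n",
    object@tauCHat, hm, object@deltaDHat, object@objective))
  cat(sprintf(
    "  mid-sleep: model %.2f vs observed %.2f; duration: model %.2f vs observed %.2f h\n",
    object@predictedMidSleep, object@observedMidSleep,
    object@predictedDuration, object@observedDuration))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Predict melatonin acrophase times from a simulation
#'
#' The model's circadian phase marker is the circadian wake-propensity
#' minimum (CWPM); the urinary aMT6s acrophase is predicted as CWPM plus
#' a fixed offset.  The default offset (0.5 h) was calibrated once
#' against the synthetic-cohort generator so that the mean residual on
#' synthetic acrophase records is zero; it can be recalibrated with
#' [calibrateAcrophaseOffset()].  Acrophase is used only for validation,
#' never in the fitting objective.
#'
#' @param sim a [SimResult-class].
#' @param offset hours added to each CWPM time (default 0.5).
#' @return POSIXct vector of predicted acrophase times (empty when the
#'   simulation has no CWPMs).
#' @export
predictAcrophase <- function(sim, offset = 0.5) {
  if (length(sim@cwpm) == 0)
    return(sim@origin[0])
  hoursToPosix(sim@cwpm + offset, sim@origin)
}

#' Calibrate the CWPM-to-acrophase offset
#'
#' Circular mean, over all observed acrophases, of the difference
#' between each observed acrophase and the nearest CWPM.
#'
#' @param sim a [SimResult-class] with at least one CWPM.
#' @param acrophases data.frame as returned by [readAcrophases()].
#' @return offset in hours.
#' @export
calibrateAcrophaseOffset <- function(sim, acrophases) {
  if (length(sim@cwpm) == 0) clInsufficientError("simulation has no CWPMs")
  obsH <- hoursSince(acrophases$acrophase, sim@origin)
  d <- vapply(obsH, function(o) o - sim@cwpm[which.min(abs(sim@cwpm - o))],
              numeric(1))
  m <- circMeanHours(d %% 24)
  circDiffHours(m, 0)
}

#' Validate predicted acrophases against observed ones
#'
#' Matches each observed acrophase record to a prediction inside its
#' collection window (the nearest one when several fall inside), then
#' summarizes agreement: the Fisher-Lee circular correlation of the
#' paired clock times, the RMSE of the paired time differences, and the
#' slope of a regression of observed on predicted times.
#'
#' @param predicted POSIXct predicted acrophase times (possibly pooled
#'   across participants).
#' @param acrophases data.frame of observed records (columns
#'   \code{windowStart}, \code{windowEnd}, \code{acrophase}).
#' @return list with \code{n}, \code{correlation}, \code{rmse} (h),
#'   \code{slope}.
#' @section Errors: fewer than 3 matched pairs raises an
#'   insufficient-data error.
#' @export
validateAcrophase <- function(predicted, acrophases) {
  predN <- as.numeric(predicted)
  pairs <- lapply(seq_len(nrow(acrophases)), function(i) {
    inWin <- which(predN >= as.numeric(acrophases$windowStart[i]) &
                     predN <= as.numeric(acrophases$windowEnd[i]))
    if (length(inWin) == 0) return(NULL)
    obs <- as.numeric(acrophases$acrophase[i])
    j <- inWin[which.min(abs(predN[inWin] - obs))]
    c(pred = predN[j], obs = obs)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) < 3)
    clInsufficientError("need at least 3 matched acrophase pairs")
  dH <- (pairs[, "obs"] - pairs[, "pred"]) / 3600
  predCk <- (pairs[, "pred"] %% 86400) / 3600
  obsCk <- (pairs[, "obs"] %% 86400) / 3600
  list(n = nrow(pairs),
       correlation = .circCorrelation(predCk / 24 * 2 * pi,
                                      obsCk / 24 * 2 * pi),
       rmse = sqrt(mean(dH^2)),
       slope = unname(coef(lm(pairs[, "obs"] ~ pairs[, "pred"]))[2]))
}

# Fisher-Lee circular correlation; NA when either margin is constant
.circCorrelation <- function(a, b) {
  n <- length(a)
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n - 1)) {
    sa <- sin(a[(i + 1):n] - a[i])
    sb <- sin(b[(i + 1):n] - b[i])
    num <- num + sum(sa * sb)
    da <- da + sum(sa^2)
    db <- db + sum(sb^2)
  }
  if (da < 1e-12 || db < 1e-12) return(NA_real_)
  num / sqrt(da * db)
}
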