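# The coupled sleep-wake / circadian / phototransduction model and its
# simulation interface.
#
# Sleep-wake switch: mutually inhibitory sleep-active (VLPO-like, V_v) and
# wake-active (monoaminergic, V_m) populations with sigmoidal firing
# rates, a homeostatic pressure H charged by wake-active firing, and a
# circadian drive C derived from the pacemaker.  Pacemaker: a van der
# Pol-type limit-cycle oscillator (x, x_c) driven by light through a
# saturating phototransduction stage n.  Light reaches the retina only
# while the model is awake (eyes-closed masking), in both imposed and
# self-selected modes.

.defaultParamValues <- c(
  tauC  = 24.2,    # intrinsic circadian period (h)
  deltaD = 0,      # wake-drive deviation (mV); + = more wake, less sleep
  Qmax  = 100,     # maximum firing rate (1/s)
  theta = 10,      # sigmoid midpoint (mV)
  sigma = 3,       # sigmoid width (mV)
  tauV  = 10,      # sleep-population time constant (s)
  tauM  = 10,      # wake-population time constant (s)
  nuVM  = -2.1,    # wake -> sleep inhibition (mV s)
  nuMV  = -1.8,    # sleep -> wake inhibition (mV s)
  nuVH  = 1.0,     # homeostatic weight (mV per pressure unit)
  nuVC  = -2.9,    # circadian weight (mV)
  Av    = -11.0,   # constant drive to the sleep-active population (mV)
  Am    = 1.3,     # constant drive to the wake-active population (mV)
  chi   = 45,      # homeostatic time constant (h)
  mu    = 4.4,     # homeostatic gain (pressure units s)
  alpha0 = 0.05,   # photic activation rate scale (1/min)
  beta  = 0.0075,  # photoreceptor recovery rate (1/min)
  I0    = 9500,    # half-saturation reference illuminance (lux)
  p     = 0.5,     # illuminance exponent
  G     = 33.75,   # photic drive gain
  k     = 0.55,    # light modulation of pacemaker stiffness
  b     = 0.4,     # light modulation by pacemaker state
  q     = 1 / 3,   # photic drive coupling to x_c
  muP   = 0.13,    # van der Pol stiffness
  f     = 0.99737, # period correction: intrinsic limit-cycle period = tauC
  phiC  = 2.0)     # phase delay (h) of the circadian wake drive vs x

#' Construct model parameters
#'
#' The two individual-specific parameters are \code{tauC}, the intrinsic
#' circadian period (hours), and \code{deltaD}, the deviation of the mean
#' drive for wakefulness from its default (mV): positive values increase
#' wake propensity and shorten sleep.  All other arguments are fixed
#' physiological constants whose defaults produce, for \code{deltaD = 0}
#' under a regular bright 24-h light routine, one consolidated sleep
#' episode of about 8 h per day, and whose intrinsic pacemaker period in
#' darkness equals \code{tauC}.
#'
#' @param tauC intrinsic circadian period in hours (must lie in
#'   \code{[22, 28]}).
#' @param deltaD wake-drive deviation in drive units (mV).
#' @param ... overrides for the fixed parameters (see
#'   \code{circalight:::.defaultParamValues} for names, defaults and
#'   units).
#' @return a [ModelParams-class].
#' @examples
#' p <- modelParams(tauC = 24.5, deltaD = -1.7)
#' tauC(p)
#' @export
modelParams <- function(tauC = 24.2, deltaD = 0, ...) {
  v <- .defaultParamValues
  v["tauC"] <- tauC
  v["deltaD"] <- deltaD
  extra <- list(...)
  if (length(extra)) {
    bad <- setdiff(names(extra), names(v))
    if (length(bad))
      clArgumentError(paste("unknown parameters:", paste(bad, collapse = ", ")))
    v[names(extra)] <- unlist(extra)
  }
  new("ModelParams", values = v)
}

#' @rdname ModelParams-class
#' @export
setMethod("tauC", "ModelParams", function(x) unname(x@values["tauC"]))

#' @rdname ModelParams-class
#' @export
setMethod("deltaD", "ModelParams", function(x) unname(x@values["deltaD"]))

setMethod("show", "ModelParams", function(object) {
  cat(sprintf("ModelParams: tauC = %.3f h, deltaD = %+.2f\n",
              object@values["tauC"], object@values["deltaD"]))
  fx <- object@values[!names(object@values) %in% c("tauC", "deltaD")]
  cat("  fixed:", paste(sprintf("%s=%g", names(fx), fx), collapse = ", "),
      "\n")
})

.stateNames <- c("Vv", "Vm", "H", "x", "xc", "n")

#' Construct a model state vector
#'
#' @param Vv,Vm mean voltages of the sleep- and wake-active populations
#'   (mV).
#' @param H homeostatic pressure.
#' @param x,xc pacemaker state (dimensionless).
#' @param n activated photoreceptor fraction in \code{[0, 1]}.
#' @return named numeric vector of length 6.
#' @export
modelState <- function(Vv = -5, Vm = 0, H = 12, x = -1, xc = 0, n = 0.1) {
  if (n < 0 || n > 1) clArgumentError("n must lie in [0, 1]")
  c(Vv = Vv, Vm = Vm, H = H, x = x, xc = xc, n = n)
}

#' Right-hand side of the model ODE system
#'
#' Returns the instantaneous rate of change of the six-dimensional state
#' for a given illuminance.  Light reaches the retina only when
#' \code{wake} is \code{TRUE}; in the dark limit the photic drive is zero
#' and the photoreceptor pool recovers at rate \code{beta}.
#'
#' @param state named numeric state vector (see [modelState()]).
#' @param params a [ModelParams-class].
#' @param lux illuminance at the eye when awake (lux, \code{>= 0}).
#' @param wake logical; is the model awake (eyes open)?
#' @return named numeric vector of time derivatives (per hour).
#' @examples
#' derivatives(modelState(), modelParams(), lux = 0)
#' @export
derivatives <- function(state, params, lux, wake = TRUE) {
  if (lux < 0) clArgumentError("lux must be >= 0")
  if (any(!is.finite(state)))
    clNumericalError("non-finite state passed to derivatives")
  d <- .derivativesCore(unname(state[.stateNames]), unname(params@values),
                        lux, wake)
  setNames(d, .stateNames)
}

#' Circadian wake-propensity drive
#'
#' The dimensionless circadian drive entering the sleep-active
#' population, \code{C = (1 + x cos(phi) - x_c sin(phi)) / 2} with
#' \code{phi = phiC * pi / 12}.  Its per-cycle minimum (the circadian
#' wake-propensity minimum, CWPM) falls in the late biological night and
#' serves as the model's circadian phase marker.
#'
#' @param x,xc pacemaker state.
#' @param params a [ModelParams-class].
#' @return numeric drive values.
#' @export
circadianDrive <- function(x, xc, params = modelParams()) {
  ph <- unname(params@values["phiC"]) * pi / 12
  0.5 * (1 + x * cos(ph) - xc * sin(ph))
}

# reference profile representing a regular bright indoor/outdoor routine;
# used to condition the default initial state and as the bright-entrainment
# reference in tests
.referenceProfile <- function() availableLightProfile(1000, 10)

.stateCache <- new.env(parent = emptyenv())

#' Entrained default steady state
#'
#' The model state at midnight after prolonged exposure of the default
#' physiology (\code{tauC = 24.2}, \code{deltaD = 0}) to the regular
#' bright reference light routine.  Used as the canonical initial state
#' of all simulations; a post-transient window absorbs the remaining
#' adjustment to other parameter values.  Computed once per session and
#' cached.
#'
#' @return named numeric state vector.
#' @export
defaultInitialState <- function() {
  if (is.null(.stateCache$y0)) {
    sim <- simulateModel(modelParams(), .referenceProfile(), days = 30,
                         initialState = modelState(), transientDays = 0)
    .stateCache$y0 <- setNames(sim@states[nrow(sim@states), ], .stateNames)
  }
  .stateCache$y0
}

#' Simulate the sleep-circadian model
#'
#' Integrates the model with piecewise-constant light per epoch.  In
#' \code{self_selected} mode the light source is an
#' [AvailableLightProfile-class] evaluated at clock time while the model
#' is awake (the model is never forced awake; it samples the available
#' light according to its own sleep timing).  In \code{imposed} mode the
#' light source is an [EpochSeries-class] of observed lux on the real
#' time axis; observed light is still zeroed during model sleep (eyes
#' closed).  Missing epochs in an imposed series are imputed by the mean
#' observed lux at the same clock time on other days.
#'
#' @param params a [ModelParams-class].
#' @param light an [AvailableLightProfile-class] or an
#'   [EpochSeries-class].
#' @param days simulation length in days (ignored for an imposed
#'   EpochSeries, which fixes the span); at least
#'   \code{transientDays + 10} for meaningful entrainment summaries.
#' @param mode \code{"self_selected"} or \code{"imposed"}; defaults to
#'   the mode implied by the class of \code{light}.
#' @param epochLength light piecewise-constancy interval in seconds
#'   (profile mode; an EpochSeries fixes its own).
#' @param initialState starting state; default [defaultInitialState()].
#' @param transientDays days discarded before computing episodes-based
#'   summaries (default 14).
#' @param dayShift optional per-day behavioral time shift (h) applied to
#'   the profile (recycled over days); used by the synthetic generator.
#' @param origin POSIXct calendar time of simulation hour zero.  Profile
#'   simulations start at midnight; imposed simulations start at the
#'   first midnight covered by the series.
#' @param rtol,atol integrator tolerances.
#' @return a [SimResult-class].
#' @examples
#' \donttest{
#' sim <- simulateModel(modelParams(), availableLightProfile(1000, 10),
#'                      days = 30)
#' modelEpisodes(sim)[1:3, ]
#' }
#' @export
simulateModel <- function(params, light, days = 42,
                          mode = c("auto", "self_selected", "imposed"),
                          epochLength = 120, initialState = NULL,
                          transientDays = 14, dayShift = NULL,
                          origin = NULL, rtol = 1e-6, atol = 1e-8) {
  mode <- match.arg(mode)
  if (is(light, "AvailableLightProfile")) {
    if (mode == "imposed")
      clArgumentError("imposed mode requires an EpochSeries light source")
    lightMode <- 1L
    lux <- numeric(0)
    profPar <- c(light@LDay, light@LEve, light@riseTime, light@peakTime,
                 light@declineTime)
    epH <- epochLength / 3600
    nEp <- as.integer(round(days * 24 / epH))
    t0 <- 0
    if (is.null(origin)) origin <- .posixctOrigin()
  } else if (is(light, "EpochSeries")) {
    if (mode == "self_selected")
      clArgumentError(
        "self_selected mode requires an AvailableLightProfile light source")
    lightMode <- 0L
    epH <- light@epochLength / 3600
    # start at the first midnight covered by the series
    ck <- clockHours(light@start)
    skip <- if (ck < 1e-9) 0L else as.integer(round((24 - ck) / epH))
    lux <- .imputeLux(light)[(skip + 1):length(light@lux)]
    nEp <- length(lux)
    t0 <- 0
    profPar <- numeric(5)
    origin <- light@start + skip * light@epochLength
    days <- nEp * epH / 24
  } else {
    clArgumentError("light must be an AvailableLightProfile or EpochSeries")
  }
  if (is.null(initialState)) initialState <- defaultInitialState()
  if (is.null(dayShift)) dayShift <- numeric(0)
  res <- .simulateCore(unname(initialState[.stateNames]), t0, nEp, epH,
                       unname(params@values), lightMode, lux, profPar,
                       dayShift, rtol, atol)
  times <- t0 + (0:nEp) * epH
  colnames(res$states) <- .stateNames

  ep <- .pairEpisodes(res$transitionTimes, res$transitionDir)
  flags <- character(0)
  post <- ep[ep$onset >= transientDays * 24, , drop = FALSE]
  op <- NA_real_
  if (nrow(post) >= 7) {
    op <- .onsetPeriodHours(post$onset)
  } else {
    flags <- c(flags, "short_for_entrainment_summary")
  }
  if (days < transientDays + 10)
    flags <- union(flags, "short_for_entrainment_summary")

  cw <- .cwpmFromTrajectory(times, res$states[, "x"], res$states[, "xc"],
                            params)
  if (length(cw) == 0) flags <- c(flags, "non_oscillatory")

  new("SimResult", times = times, states = res$states,
      wake = as.logical(res$wakeAt), episodes = ep, cwpm = cw,
      receivedLux = as.numeric(res$received), onsetPeriod = op,
      transientDays = transientDays,
      origin = if (is.null(origin)) .posixctOrigin() else origin,
      flags = flags)
}

# impute masked epochs with the mean observed lux at the same clock time
# on other days, so imposed-mode simulations see a typical day rather
# than spurious darkness
.imputeLux <- function(series) {
  lux <- series@lux
  bad <- series@missing | is.na(lux)
  if (!any(bad)) return(lux)
  epH <- series@epochLength / 3600
  slot <- (floor(clockHours(series@start) / epH) +
             seq_along(lux) - 1) %% (24 / epH)
  typical <- tapply(lux[!bad], slot[!bad], mean)
  fill <- typical[as.character(slot[bad])]
  fill[is.na(fill)] <- 0
  lux[bad] <- fill
  lux
}

.pairEpisodes <- function(transT, transDir) {
  on <- transT[transDir == -1]
  off <- transT[transDir == +1]
  if (length(on) == 0 || length(off) == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  # drop an offset that precedes the first onset (episode already in
  # progress at start) and an onset with no terminating offset
  off <- off[off > on[1]]
  k <- min(length(on), length(off))
  data.frame(onset = on[seq_len(k)], offset = off[seq_len(k)])
}

.onsetPeriodHours <- function(onsets) {
  unname(coef(lm(onsets ~ seq_along(onsets)))[2])
}

# per-cycle minima of the circadian wake-propensity drive, refined by
# quadratic interpolation on the epoch grid.  Light input superimposes
# small wiggles on the limit cycle, so candidate minima are restricted
# to the deep half of the drive's range and minima closer than 16 h
# collapse to the deeper one.
.cwpmFromTrajectory <- function(times, x, xc, params) {
  C <- circadianDrive(x, xc, params)
  if (diff(range(x)) < 0.2) return(numeric(0))
  n <- length(C)
  if (n < 3) return(numeric(0))
  i <- which(C[2:(n - 1)] <= C[1:(n - 2)] & C[2:(n - 1)] < C[3:n]) + 1
  i <- i[C[i] < (max(C) + min(C)) / 2]
  if (length(i) == 0) return(numeric(0))
  dt <- times[2] - times[1]
  refine <- function(j) {
    y1 <- C[j - 1]; y2 <- C[j]; y3 <- C[j + 1]
    den <- y1 - 2 * y2 + y3
    d <- if (abs(den) < 1e-15) 0 else 0.5 * (y1 - y3) / den
    times[j] + max(-0.5, min(0.5, d)) * dt
  }
  tm <- vapply(i, refine, numeric(1))
  vm <- C[i]
  # merge clusters closer than two-thirds of a cycle
  keep <- rep(TRUE, length(tm))
  for (j in seq_along(tm)[-1]) {
    prev <- max(which(keep[1:(j - 1)]))
    if (tm[j] - tm[prev] < 16) {
      if (vm[j] < vm[prev]) keep[prev] <- FALSE else keep[j] <- FALSE
    }
  }
  tm[keep]
}

#' @rdname SimResult-class
#' @export
setMethod("modelEpisodes", "SimResult", function(x) x@episodes)

#' @describeIn cwpmTimes times (hours from simulation start) of the
#'   circadian wake-propensity minima, one per circadian cycle; empty
#'   (with a \code{"non_oscillatory"} flag on the result) when the
#'   pacemaker trajectory does not oscillate.
#' @export
setMethod("cwpmTimes", "SimResult", function(x) x@cwpm)

#' @describeIn onsetPeriod onset period of the post-transient model sleep
#'   episodes.
setMethod("onsetPeriod", "SimResult", function(x, ...) {
  ep <- x@episodes
  post <- ep[ep$onset >= x@transientDays * 24, , drop = FALSE]
  if (nrow(post) < 7)
    clInsufficientError("need at least 7 post-transient episodes")
  .onsetPeriodHours(post$onset)
})

#' @describeIn onsetPeriod onset period of recorded (e.g. diary) sleep
#'   episodes.
setMethod("onsetPeriod", "SleepEpisodes", function(x, ...) {
  if (nEpisodes(x) < 7) clInsufficientError("need at least 7 episodes")
  .onsetPeriodHours(as.numeric(x@onset) / 3600)
})

#' @describeIn onsetPeriod onset period of a numeric vector of onset
#'   hours.
setMethod("onsetPeriod", "numeric", function(x, ...) {
  if (length(x) < 7) clInsufficientError("need at least 7 onsets")
  .onsetPeriodHours(x)
})

setMethod("show", "SimResult", function(object) {
  nd <- (length(object@times) - 1) * diff(object@times[1:2]) / 24
  cat(sprintf("SimResult: %.1f days, %d sleep episodes, %d CWPMs\n",
              nd, nrow(object@episodes), length(object@cwpm)))
  if (!is.na(object@onsetPeriod))
    cat(sprintf("  post-transient onset period %.4f h\n",
                object@onsetPeriod))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
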