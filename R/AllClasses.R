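# S4 class definitions.  All datetimes are naive local time stored as
# POSIXct in the UTC timezone; simulations use a numeric hour axis whose
# zero is midnight of an (optional) calendar origin.

.posixctOrigin <- function() as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

#' EpochSeries: a uniformly sampled rest-activity and light recording
#'
#' Holds per-epoch activity counts and illuminance (lux) sampled at a fixed
#' epoch length, gap-free: epochs with no usable data are present but
#' flagged in the missing mask, never omitted.  Epoch intervals are
#' half-open \code{[t, t + epochLength)}.
#'
#' @slot start POSIXct start of the first epoch.
#' @slot epochLength epoch length in seconds; must divide 24 h exactly.
#' @slot activity numeric vector of non-negative per-epoch activity counts.
#' @slot lux numeric vector of non-negative per-epoch illuminance (lux).
#' @slot missing logical mask; \code{TRUE} marks epochs without data.
#' @seealso [epochSeries()], [readRecording()]
#' @export
setClass("EpochSeries",
         slots = c(start = "POSIXct", epochLength = "numeric",
                   activity = "numeric", lux = "numeric",
                   missing = "logical"))

setValidity("EpochSeries", function(object) {
  msg <- character(0)
  n <- length(object@activity)
  if (length(object@lux) != n || length(object@missing) != n)
    msg <- c(msg, "activity, lux and missing must have equal length")
  if (length(object@epochLength) != 1 || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be a single positive number of seconds")
  else if (abs(86400 / object@epochLength -
               round(86400 / object@epochLength)) > 1e-9)
    msg <- c(msg, "epochLength must divide 24 h exactly")
  ok <- !object@missing
  if (any(object@activity[ok] < 0, na.rm = TRUE) ||
      any(object@lux[ok] < 0, na.rm = TRUE))
    msg <- c(msg, "non-missing activity and lux values must be >= 0")
  if (length(object@start) != 1 || is.na(object@start))
    msg <- c(msg, "start must be a single POSIXct")
  if (length(msg)) msg else TRUE
})

#' SleepEpisodes: a chronological set of sleep onset-offset intervals
#'
#' One row per sleep episode on the real-time axis.  Episodes are
#' time-ordered and non-overlapping, each shorter than 24 h.
#'
#' @slot onset POSIXct sleep onsets.
#' @slot offset POSIXct sleep offsets (\code{offset > onset}).
#' @slot source character, each \code{"diary"} or \code{"model"}.
#' @seealso [sleepEpisodes()], [readDiary()]
#' @export
setClass("SleepEpisodes",
         slots = c(onset = "POSIXct", offset = "POSIXct",
                   source = "character"))

setValidity("SleepEpisodes", function(object) {
  msg <- character(0)
  n <- length(object@onset)
  if (length(object@offset) != n || length(object@source) != n)
    msg <- c(msg, "onset, offset and source must have equal length")
  if (n > 0) {
    if (any(!object@source %in% c("diary", "model")))
      msg <- c(msg, "source must be 'diary' or 'model'")
    dur <- as.numeric(object@offset) - as.numeric(object@onset)
    if (any(dur <= 0)) msg <- c(msg, "every offset must be after its onset")
    if (any(dur >= 86400)) msg <- c(msg, "episode durations must be < 24 h")
    if (n > 1) {
      if (is.unsorted(as.numeric(object@onset), strictly = FALSE))
        msg <- c(msg, "episodes must be in chronological order")
      else if (any(as.numeric(object@onset[-1]) <
                   as.numeric(object@offset[-n])))
        msg <- c(msg, "episodes must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ParticipantRecord: one participant's complete dataset
#'
#' Bundles the actigraphy/light recording, diary sleep episodes and
#' melatonin acrophase records of one participant.
#'
#' @slot id character participant identifier.
#' @slot group character, \code{"case"} or \code{"control"}.
#' @slot recording an [EpochSeries-class].
#' @slot episodes a [SleepEpisodes-class].
#' @slot acrophases data.frame with POSIXct columns \code{windowStart},
#'   \code{windowEnd}, \code{acrophase}; each acrophase lies inside its
#'   collection window.
#' @export
setClass("ParticipantRecord",
         slots = c(id = "character", group = "character",
                   recording = "EpochSeries", episodes = "SleepEpisodes",
                   acrophases = "data.frame"))

setValidity("ParticipantRecord", function(object) {
  msg <- character(0)
  if (length(object@id) != 1) msg <- c(msg, "id must be a single string")
  if (!object@group %in% c("case", "control"))
    msg <- c(msg, "group must be 'case' or 'control'")
  a <- object@acrophases
  if (nrow(a) > 0) {
    need <- c("windowStart", "windowEnd", "acrophase")
    if (!all(need %in% names(a)))
      msg <- c(msg, "acrophases needs windowStart, windowEnd, acrophase")
    else if (any(a$acrophase < a$windowStart | a$acrophase > a$windowEnd))
      msg <- c(msg, "each acrophase must lie within its collection window")
  }
  rec <- object@recording
  span <- as.numeric(rec@start) +
    c(0, length(rec@activity) * rec@epochLength)
  ep <- object@episodes
  if (length(ep@onset) > 0 &&
      (any(as.numeric(ep@onset) < span[1]) ||
       any(as.numeric(ep@offset) > span[2])))
    msg <- c(msg, "episodes must fall within the recording span")
  if (length(msg)) msg else TRUE
})

#' ModelParams: parameters of the sleep-circadian model
#'
#' The two individual-specific parameters are the intrinsic circadian
#' period \code{tauC} (hours) and the wake-drive deviation \code{deltaD}
#' (drive units, mV): positive \code{deltaD} means more drive for
#' wakefulness and hence shorter sleep.  The remaining entries are fixed
#' physiological constants of the sleep-wake switch (firing-rate sigmoid,
#' population time constants, mutual-inhibition and homeostatic weights)
#' and of the photic pathway (phototransduction rates, pacemaker
#' light-coupling and stiffness).  See [modelParams()] for the defaults
#' and units.
#'
#' @slot values named numeric vector of all parameters, fixed order.
#' @seealso [modelParams()], [simulateModel()]
#' @export
setClass("ModelParams", slots = c(values = "numeric"))

.paramNames <- c("tauC", "deltaD", "Qmax", "theta", "sigma", "tauV",
                 "tauM", "nuVM", "nuMV", "nuVH", "nuVC", "Av", "Am",
                 "chi", "mu", "alpha0", "beta", "I0", "p", "G", "k", "b",
                 "q", "muP", "f", "phiC")

setValidity("ModelParams", function(object) {
  v <- object@values
  msg <- character(0)
  if (!identical(names(v), .paramNames))
    return("values must be named exactly as circalight:::.paramNames")
  if (any(!is.finite(v))) msg <- c(msg, "all parameters must be finite")
  if (v["tauC"] < 22 || v["tauC"] > 28)
    msg <- c(msg, "tauC must lie in [22, 28] h")
  pos <- c("Qmax", "sigma", "tauV", "tauM", "chi", "mu", "alpha0", "beta",
           "I0", "p", "G", "f")
  if (any(v[pos] <= 0))
    msg <- c(msg, "rate constants and gains must be positive")
  if (length(msg)) msg else TRUE
})

#' AvailableLightProfile: a parametric 24-h light-availability curve
#'
#' Environmental light a person could be exposed to if awake: a raised
#' cosine that climbs from the evening floor \code{LEve} starting at
#' \code{riseTime}, attains its maximum \code{LDay} at \code{peakTime} and
#' returns to \code{LEve} by \code{declineTime}; \code{LEve} holds through
#' the rest of the evening and night.  The curve is 24-h periodic and
#' continuous.
#'
#' @slot LDay peak daytime illuminance (lux), \code{LDay >= LEve}.
#' @slot LEve evening/night illuminance (lux), \code{>= 0}.
#' @slot riseTime,peakTime,declineTime clock hours of the start of the
#'   morning rise, the midday peak, and the completed evening decline.
#' @seealso [availableLightProfile()], [profileIlluminance()]
#' @export
setClass("AvailableLightProfile",
         slots = c(LDay = "numeric", LEve = "numeric", riseTime = "numeric",
                   peakTime = "numeric", declineTime = "numeric"))

setValidity("AvailableLightProfile", function(object) {
  msg <- character(0)
  if (object@LEve < 0) msg <- c(msg, "LEve must be >= 0")
  if (object@LDay < object@LEve) msg <- c(msg, "LDay must be >= LEve")
  tt <- c(object@riseTime, object@peakTime, object@declineTime)
  if (any(tt < 0) || any(tt > 24) || any(diff(tt) <= 0))
    msg <- c(msg, "need 0 <= riseTime < peakTime < declineTime <= 24")
  if (length(msg)) msg else TRUE
})

#' SimResult: output of one model simulation
#'
#' @slot times numeric hour grid (epoch boundaries) from simulation start.
#' @slot states numeric matrix, one row per time point, columns
#'   \code{Vv, Vm, H, x, xc, n}.
#' @slot wake logical wake indicator at each time point.
#' @slot episodes data.frame of model sleep episodes with numeric hour
#'   columns \code{onset}, \code{offset} (transition times refined to
#'   sub-second precision).
#' @slot cwpm numeric hours of the circadian wake-propensity minima, one
#'   per circadian cycle.
#' @slot receivedLux numeric per-epoch mean illuminance that actually
#'   reached the retina (zero while the model slept).
#' @slot onsetPeriod numeric, slope-based period of sleep onsets (h) over
#'   the post-transient window; \code{NA} when too few episodes.
#' @slot transientDays numeric, days discarded before summaries.
#' @slot origin POSIXct calendar time of hour zero.
#' @slot flags character vector of diagnostic flags.
#' @seealso [simulateModel()]
#' @export
setClass("SimResult",
         slots = c(times = "numeric", states = "matrix", wake = "logical",
                   episodes = "data.frame", cwpm = "numeric",
                   receivedLux = "numeric", onsetPeriod = "numeric",
                   transientDays = "numeric", origin = "POSIXct",
                   flags = "character"))

#' PeriodScan: residual variance of folding at candidate periods
#'
#' Result of the non-parametric dominant-period search: the recording is
#' folded at each candidate period, epochs are phase-binned, and the
#' pooled within-bin variance is expressed as a fraction of total
#' variance.  The candidate with the smallest residual variance is the
#' dominant period.
#'
#' @slot candidatePeriods numeric candidate periods (h).
#' @slot residualVariance numeric in \code{[0, 1]}, one per candidate.
#' @slot dominantPeriod numeric, candidate minimizing residual variance
#'   (ties broken toward the smallest period).
#' @slot depth numeric diagnostic: minimum / median residual variance
#'   (near 1 for aperiodic signals).
#' @slot sparseBins integer, number of phase bins with fewer than two
#'   samples at the dominant period.
#' @seealso [foldPeriodScan()]
#' @export
setClass("PeriodScan",
         slots = c(candidatePeriods = "numeric",
                   residualVariance = "numeric", dominantPeriod = "numeric",
                   depth = "numeric", sparseBins = "integer"))

setValidity("PeriodScan", function(object) {
  msg <- character(0)
  if (length(object@residualVariance) != length(object@candidatePeriods))
    msg <- c(msg, "one residual variance per candidate period")
  rv <- object@residualVariance
  if (any(rv < -1e-9 | rv > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "residual variance must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CircularTimeStats: circular summary of a set of clock times
#'
#' @slot meanTime circular mean clock time in \code{[0, 24)} hours
#'   (\code{NA} when the resultant length is zero).
#' @slot resultantLength mean resultant length in \code{[0, 1]}.
#' @slot circularVariance \code{1 - resultantLength}.
#' @slot circularSD circular standard deviation in hours,
#'   \code{(24 / 2 pi) * sqrt(-2 log R)}.
#' @slot n integer number of times summarized.
#' @slot flags character; \code{"undefined_mean"} when R is zero.
#' @seealso [circularTimeStats()]
#' @export
setClass("CircularTimeStats",
         slots = c(meanTime = "numeric", resultantLength = "numeric",
                   circularVariance = "numeric", circularSD = "numeric",
                   n = "integer", flags = "character"))

#' LightMetrics: per-participant light-exposure summary
#'
#' Median across calendar days of (i) hours of bright light (lux strictly
#' above the threshold), (ii) mean daily lux, (iii) mean daily
#' log(lux + 1).
#'
#' @slot medianBrightHours hours/day with lux above the bright threshold.
#' @slot medianDailyLux median across days of the daily mean lux.
#' @slot medianDailyLogLux median across days of the daily mean
#'   log(lux + 1).
#' @slot brightThreshold lux threshold used (strict inequality).
#' @slot nDays integer number of complete days summarized.
#' @seealso [lightMetrics()]
#' @export
setClass("LightMetrics",
         slots = c(medianBrightHours = "numeric", medianDailyLux = "numeric",
                   medianDailyLogLux = "numeric", brightThreshold = "numeric",
                   nDays = "integer"))

setValidity("LightMetrics", function(object) {
  msg <- character(0)
  if (object@medianBrightHours < 0 || object@medianBrightHours > 24)
    msg <- c(msg, "medianBrightHours must lie in [0, 24]")
  if (object@medianDailyLux < 0 || object@medianDailyLogLux < 0)
    msg <- c(msg, "light metrics must be non-negative")
  if (length(msg)) msg else TRUE
})

#' EntrainmentMap: entrainment classification over a light-intensity grid
#'
#' Long-format grid over (daytime peak lux, evening lux): for every
#' combination, whether the simulated sleep-onset period is within
#' tolerance of 24 h, the onset period itself, and (for entrained points
#' only) the circular mean sleep offset.
#'
#' @slot grid data.frame with columns \code{LDay}, \code{LEve},
#'   \code{entrained}, \code{onsetPeriod}, \code{meanOffset},
#'   \code{failed}.
#' @slot tauC,deltaD the physiology the map was computed for.
#' @slot tol entrainment tolerance on the onset period (h).
#' @seealso [entrainmentMap()], [designIntervention()]
#' @export
setClass("EntrainmentMap",
         slots = c(grid = "data.frame", tauC = "numeric", deltaD = "numeric",
                   tol = "numeric"))

#' FitResult: per-individual parameter estimates
#'
#' @slot tauCHat fitted intrinsic circadian period (h).
#' @slot deltaDHat fitted wake-drive deviation (drive units).
#' @slot objective objective value at the optimum.
#' @slot predictedMidSleep model circular mean mid-sleep (clock h).
#' @slot predictedDuration model mean sleep duration (h).
#' @slot observedMidSleep,observedDuration the matched observed values.
#' @slot predictedAcrophase POSIXct model-predicted acrophase times.
#' @slot searchBox numeric \code{c(tauC lo, tauC hi, deltaD lo, deltaD hi)}.
#' @slot convergence list of optimizer diagnostics (grid best, refinement
#'   path, near-optimal basins).
#' @slot flags character; may include \code{"boundary"},
#'   \code{"multimodal"}, \code{"no_convergence"}.
#' @seealso [fitParticipant()]
#' @export
setClass("FitResult",
         slots = c(tauCHat = "numeric", deltaDHat = "numeric",
                   objective = "numeric", predictedMidSleep = "numeric",
                   predictedDuration = "numeric",
                   observedMidSleep = "numeric",
                   observedDuration = "numeric",
                   predictedAcrophase = "POSIXct",
                   searchBox = "numeric", convergence = "list",
                   flags = "character"))

#' CohortConfig: configuration of the synthetic cohort generator
#'
#' Group sizes, the per-group distributions of the latent physiology
#' (intrinsic period, wake drive), per-group light environments, noise
#' levels, the activity count model, and the recording geometry.  All
#' stochastic draws descend deterministically from \code{seed}.
#'
#' @slot nCases,nControls integer group sizes.
#' @slot tauCMean,tauCSD named numeric (case, control), hours.
#' @slot deltaDMean,deltaDSD named numeric (case, control), drive units.
#' @slot caseProfile,controlProfile [AvailableLightProfile-class] light
#'   environments.
#' @slot lightJitterSD per-day SD of the behavioral shift of the light
#'   profile (h).
#' @slot diaryJitterSD SD of diary reporting jitter on onset/offset (h).
#' @slot luxSigma multiplicative log-normal sigma of lux measurement.
#' @slot acrophaseOffset fixed offset from CWPM to aMT6s acrophase (h).
#' @slot acrophaseNoiseSD SD of acrophase measurement noise (h).
#' @slot wakeCounts,sleepCounts mean activity counts per epoch.
#' @slot countDispersion negative-binomial size parameter.
#' @slot epochLength seconds; \code{days} recording length; \code{seed}
#'   master seed.
#' @slot days numeric recording length in days.
#' @slot seed integer master seed.
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
         slots = c(nCases = "integer", nControls = "integer",
                   tauCMean = "numeric", tauCSD = "numeric",
                   deltaDMean = "numeric", deltaDSD = "numeric",
                   caseProfile = "AvailableLightProfile",
                   controlProfile = "AvailableLightProfile",
                   lightJitterSD = "numeric", diaryJitterSD = "numeric",
                   luxSigma = "numeric", acrophaseOffset = "numeric",
                   acrophaseNoiseSD = "numeric", wakeCounts = "numeric",
                   sleepCounts = "numeric", countDispersion = "numeric",
                   epochLength = "numeric", days = "numeric",
                   seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  sds <- c(object@tauCSD, object@deltaDSD, object@lightJitterSD,
           object@diaryJitterSD, object@luxSigma, object@acrophaseNoiseSD)
  if (any(sds < 0)) msg <- c(msg, "all SDs must be >= 0")
  if (object@days < 28) msg <- c(msg, "days must be >= 28")
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "a seed is mandatory")
  for (s in c("tauCMean", "tauCSD", "deltaDMean", "deltaDSD")) {
    v <- slot(object, s)
    if (!all(c("case", "control") %in% names(v)))
      msg <- c(msg, sprintf("%s needs named entries 'case' and 'control'", s))
  }
  if (length(msg)) msg else TRUE
})
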