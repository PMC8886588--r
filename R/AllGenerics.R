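# Generics for accessors shared across classes.

#' @rdname EpochSeries-class
#' @param x an object.
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname EpochSeries-class
#' @export
setGeneric("epochLength", function(x) standardGeneric("epochLength"))

#' @rdname EpochSeries-class
#' @export
setGeneric("activityCounts", function(x) standardGeneric("activityCounts"))

#' @rdname EpochSeries-class
#' @export
setGeneric("luxValues", function(x) standardGeneric("luxValues"))

#' @rdname EpochSeries-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname EpochSeries-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname EpochSeries-class
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname ModelParams-class
#' @param x an object.
#' @export
setGeneric("tauC", function(x) standardGeneric("tauC"))

#' @rdname ModelParams-class
#' @export
setGeneric("deltaD", function(x) standardGeneric("deltaD"))

#' @rdname SimResult-class
#' @param x an object.
#' @export
setGeneric("modelEpisodes", function(x) standardGeneric("modelEpisodes"))

#' @rdname SimResult-class
#' @export
setGeneric("cwpmTimes", function(x) standardGeneric("cwpmTimes"))

#' Sleep-onset period of a sequence of sleep episodes
#'
#' The period (hours) of the sleep-onset rhythm, estimated as the slope of
#' a linear regression of successive onset times (on a continuous hour
#' axis, so drift across midnight is unwrapped automatically) on episode
#' index.  An entrained sleeper yields 24.0; a free-running sleeper whose
#' onsets drift by +30 min/day yields 24.5.
#'
#' @param x a [SimResult-class], a [SleepEpisodes-class], or a numeric
#'   vector of onset times in hours.
#' @param ... unused.
#' @return period in hours.
#' @examples
#' onsetPeriod(seq(23, by = 24.5, length.out = 10))  # drifts 30 min/day
#' @export
setGeneric("onsetPeriod", function(x, ...) standardGeneric("onsetPeriod"))
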