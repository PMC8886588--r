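# Reading, writing and validating recordings, diaries and acrophase
# records.  CSV dialects:
#   recording: timestamp,activity,lux          (ISO-8601 timestamps)
#   diary:     date,onset_time,offset_time     (clock times; offset may
#                                               roll to the next day)
#   acrophase: window_start,window_end,acrophase_time

.parseISO <- function(x, what) {
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                 "%Y-%m-%d"),
                  optional = TRUE)
  if (any(is.na(t) & !is.na(x)))
    clFormatError(sprintf("unparseable %s timestamp: '%s'", what,
                          x[which(is.na(t) & !is.na(x))[1]]))
  t
}

#' Construct an EpochSeries
#'
#' @param start POSIXct (or ISO-8601 string) start of the first epoch.
#' @param activity,lux numeric per-epoch values.
#' @param epochLength epoch length in seconds (default 120, i.e. 2-min
#'   epochs).
#' @param missing logical mask of epochs without data; such epochs are
#'   excluded from all metric computations (zero lux is meaningful
#'   darkness, not missingness).
#' @return an [EpochSeries-class].
#' @examples
#' es <- epochSeries("2024-01-01", activity = rpois(720, 100),
#'                   lux = rep(100, 720))
#' es
#' @export
epochSeries <- function(start, activity, lux, epochLength = 120,
                        missing = rep(FALSE, length(activity))) {
  if (is.character(start)) start <- .parseISO(start, "start")
  act <- as.numeric(activity)
  lx <- as.numeric(lux)
  act[missing] <- NA_real_
  lx[missing] <- NA_real_
  new("EpochSeries", start = start, epochLength = as.numeric(epochLength),
      activity = act, lux = lx, missing = as.logical(missing))
}

#' @rdname EpochSeries-class
#' @export
setMethod("startTime", "EpochSeries", function(x) x@start)

#' @rdname EpochSeries-class
#' @export
setMethod("epochLength", "EpochSeries", function(x) x@epochLength)

#' @rdname EpochSeries-class
#' @export
setMethod("activityCounts", "EpochSeries", function(x) x@activity)

#' @rdname EpochSeries-class
#' @export
setMethod("luxValues", "EpochSeries", function(x) x@lux)

#' @rdname EpochSeries-class
#' @export
setMethod("missingMask", "EpochSeries", function(x) x@missing)

#' @rdname EpochSeries-class
#' @export
setMethod("nEpochs", "EpochSeries", function(x) length(x@activity))

#' @rdname EpochSeries-class
#' @export
setMethod("epochTimes", "EpochSeries", function(x) {
  x@start + (seq_along(x@activity) - 1) * x@epochLength
})

setMethod("show", "EpochSeries", function(object) {
  n <- length(object@activity)
  cat(sprintf("EpochSeries: %d epochs of %gs (%.1f days) from %s\n",
              n, object@epochLength, n * object@epochLength / 86400,
              format(object@start, "%Y-%m-%d %H:%M")))
  cat(sprintf("  missing: %d epochs (%.1f%%)\n", sum(object@missing),
              100 * mean(object@missing)))
  if (any(!object@missing))
    cat(sprintf("  lux: median %.1f, max %.0f; activity: median %.0f\n",
                median(object@lux, na.rm = TRUE),
                max(object@lux, na.rm = TRUE),
                median(object@activity, na.rm = TRUE)))
})

#' Construct a SleepEpisodes object
#'
#' @param onset,offset POSIXct (or ISO-8601 string) vectors.
#' @param source \code{"diary"} or \code{"model"}, recycled.
#' @return a [SleepEpisodes-class].
#' @export
sleepEpisodes <- function(onset, offset, source = "diary") {
  if (is.character(onset)) onset <- .parseISO(onset, "onset")
  if (is.character(offset)) offset <- .parseISO(offset, "offset")
  ord <- order(as.numeric(onset))
  new("SleepEpisodes", onset = onset[ord], offset = offset[ord],
      source = rep_len(source, length(onset)))
}

#' @rdname SleepEpisodes-class
#' @param x a SleepEpisodes object.
#' @return \code{episodeTable()} returns a data.frame with columns
#'   \code{onset}, \code{offset}, \code{duration} (h), \code{midSleep}
#'   (POSIXct) and \code{source}.
#' @export
episodeTable <- function(x) {
  dur <- (as.numeric(x@offset) - as.numeric(x@onset)) / 3600
  data.frame(onset = x@onset, offset = x@offset, duration = dur,
             midSleep = x@onset + dur * 1800, source = x@source)
}

#' @rdname SleepEpisodes-class
#' @param object a SleepEpisodes object.
#' @export
nEpisodes <- function(object) length(object@onset)

setMethod("show", "SleepEpisodes", function(object) {
  n <- length(object@onset)
  cat(sprintf("SleepEpisodes: %d episodes (%s)\n", n,
              paste(unique(object@source), collapse = ", ")))
  if (n > 0) {
    dur <- (as.numeric(object@offset) - as.numeric(object@onset)) / 3600
    cat(sprintf("  duration mean %.2f h (range %.2f-%.2f)\n",
                mean(dur), min(dur), max(dur)))
  }
})

#' Construct a ParticipantRecord
#'
#' @param id participant identifier.
#' @param group \code{"case"} or \code{"control"}.
#' @param recording an [EpochSeries-class].
#' @param episodes a [SleepEpisodes-class].
#' @param acrophases data.frame with POSIXct columns \code{windowStart},
#'   \code{windowEnd}, \code{acrophase} (may be empty).
#' @return a [ParticipantRecord-class].
#' @export
participantRecord <- function(id, group, recording, episodes,
                              acrophases = data.frame()) {
  new("ParticipantRecord", id = as.character(id), group = group,
      recording = recording, episodes = episodes, acrophases = acrophases)
}

setMethod("show", "ParticipantRecord", function(object) {
  cat(sprintf("ParticipantRecord '%s' (%s)\n", object@id, object@group))
  show(object@recording)
  show(object@episodes)
  cat(sprintf("  acrophase records: %d\n", nrow(object@acrophases)))
})

#' Read an epoch-based actigraphy + light recording
#'
#' Reads a CSV with columns \code{timestamp}, \code{activity}, \code{lux}
#' and returns a gap-free [EpochSeries-class]: rows missing from the file
#' become masked epochs, and rows that do not fall on the declared epoch
#' grid are resampled by left-edge alignment (each row is assigned to the
#' epoch whose half-open interval contains its timestamp; multiple rows in
#' one epoch are averaged).
#'
#' @param path CSV file path.
#' @param epochLength declared epoch length in seconds (default 120).
#' @return an [EpochSeries-class].
#' @section Errors: unparseable timestamps raise a format error; duplicate
#'   timestamps a data error; a file spanning less than 24 h an
#'   insufficient-data error.
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, epochLength = 120) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "activity", "lux")
  if (!all(need %in% names(d)))
    clFormatError("recording CSV must have columns timestamp, activity, lux")
  t <- .parseISO(d$timestamp, "recording")
  if (anyDuplicated(as.numeric(t)))
    clDataError("duplicate timestamps in recording")
  if (diff(range(as.numeric(t))) < 86400 - epochLength)
    clInsufficientError("recording spans less than 24 h")
  t0 <- min(t)
  idx <- floor((as.numeric(t) - as.numeric(t0)) / epochLength)
  n <- max(idx) + 1
  act <- rep(NA_real_, n)
  lx <- rep(NA_real_, n)
  cnt <- tabulate(idx + 1, nbins = n)
  sAct <- rep(0, n); sLux <- rep(0, n)
  sAct[sort(unique(idx)) + 1] <- rowsum(d$activity, idx)[, 1]
  sLux[sort(unique(idx)) + 1] <- rowsum(d$lux, idx)[, 1]
  filled <- cnt > 0
  act[filled] <- sAct[filled] / cnt[filled]
  lx[filled] <- sLux[filled] / cnt[filled]
  epochSeries(t0, act, lx, epochLength = epochLength, missing = !filled)
}

#' Write an EpochSeries to the recording CSV dialect
#'
#' Masked epochs are written as absent rows, so
#' \code{readRecording(writeRecording(x))} reconstructs the mask.
#'
#' @param series an [EpochSeries-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(series, path) {
  keep <- !series@missing
  t <- epochTimes(series)[keep]
  d <- data.frame(timestamp = format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                  activity = series@activity[keep],
                  lux = series@lux[keep])
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sleep diary
#'
#' Reads a CSV with columns \code{date}, \code{onset_time},
#' \code{offset_time} (clock times \code{HH:MM} or \code{HH:MM:SS}).  An
#' offset at or before its onset is rolled to the next calendar day, so a
#' row \code{2024-01-01,23:30,07:30} yields one episode spanning midnight
#' with duration 8 h.
#'
#' @param path CSV file path.
#' @return a [SleepEpisodes-class] with source \code{"diary"}.
#' @section Errors: overlapping episodes raise a data error.
#' @seealso [writeDiary()]
#' @export
readDiary <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "onset_time", "offset_time")
  if (!all(need %in% names(d)))
    clFormatError("diary CSV must have columns date, onset_time, offset_time")
  onset <- .parseISO(paste(d$date, d$onset_time), "diary onset")
  offset <- .parseISO(paste(d$date, d$offset_time), "diary offset")
  roll <- as.numeric(offset) <= as.numeric(onset)
  offset[roll] <- offset[roll] + 86400
  ep <- tryCatch(sleepEpisodes(onset, offset, source = "diary"),
                 error = function(e) clDataError(conditionMessage(e)))
  ep
}

#' Write a SleepEpisodes object to the diary CSV dialect
#'
#' @param episodes a [SleepEpisodes-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDiary <- function(episodes, path) {
  d <- data.frame(date = format(episodes@onset, "%Y-%m-%d", tz = "UTC"),
                  onset_time = format(episodes@onset, "%H:%M:%S",
                                      tz = "UTC"),
                  offset_time = format(episodes@offset, "%H:%M:%S",
                                       tz = "UTC"))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read acrophase records
#'
#' Reads a CSV with columns \code{window_start}, \code{window_end},
#' \code{acrophase_time}; each acrophase must lie inside its collection
#' window.
#'
#' @param path CSV file path.
#' @return data.frame with POSIXct columns \code{windowStart},
#'   \code{windowEnd}, \code{acrophase}.
#' @export
readAcrophases <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("window_start", "window_end", "acrophase_time")
  if (!all(need %in% names(d)))
    clFormatError(
      "acrophase CSV must have columns window_start, window_end, acrophase_time")
  out <- data.frame(windowStart = .parseISO(d$window_start, "window start"),
                    windowEnd = .parseISO(d$window_end, "window end"),
                    acrophase = .parseISO(d$acrophase_time, "acrophase"))
  if (any(out$acrophase < out$windowStart | out$acrophase > out$windowEnd))
    clDataError("acrophase outside its collection window")
  out
}

#' Write acrophase records
#'
#' @param acrophases data.frame as returned by [readAcrophases()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeAcrophases <- function(acrophases, path) {
  f <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  d <- data.frame(window_start = f(acrophases$windowStart),
                  window_end = f(acrophases$windowEnd),
                  acrophase_time = f(acrophases$acrophase))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
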