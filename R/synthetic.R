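# Synthetic cohort generator: participant datasets (recording + diary +
# acrophases) with known latent physiology, so the whole pipeline can be
# validated end to end without access to any real recording.

# run code with a local, seeded RNG; the caller's RNG state is untouched
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.rnormTrunc <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))
}

#' Configure the synthetic cohort generator
#'
#' Defaults emulate a six-week, two-group observational study: the case
#' group has a markedly reduced mean wake drive (mean -1.82, SD 1.62
#' drive units) and lives in a dim light environment (peak 160 lux, 30
#' lux evenings); the control group has a slightly positive wake drive
#' (mean 0.66, SD 0.62) and a bright environment (peak 800 lux, 10 lux
#' evenings).  Intrinsic periods are drawn from nearly identical
#' distributions in both groups (case 24:14 +/- 0:12 h:m, control 24:13
#' +/- 0:10 h:m): group differences in sleep phenotype then arise from
#' drive and light, not from the circadian period.  Draws are truncated
#' to physiologically plausible ranges (tauC to [23.6, 25.4] h, deltaD
#' to [-4.5, 2.5]).
#'
#' @param nCases,nControls group sizes (defaults 20 and 21).
#' @param tauCMean,tauCSD,deltaDMean,deltaDSD named numeric
#'   \code{c(case = , control = )} distribution parameters (hours /
#'   drive units).
#' @param caseProfile,controlProfile [AvailableLightProfile-class] light
#'   environments.
#' @param lightJitterSD per-day SD (h) of the behavioral time shift of
#'   the whole light profile (adherence jitter; default 0.5 h).
#' @param diaryJitterSD SD (h) of diary reporting jitter on each onset
#'   and offset (default 0.25 h).
#' @param luxSigma sigma of multiplicative log-normal lux measurement
#'   noise (default 0.3).
#' @param acrophaseOffset fixed CWPM-to-acrophase offset (h, default
#'   0.5).
#' @param acrophaseNoiseSD SD (h) of acrophase measurement noise
#'   (default 0.5).
#' @param wakeCounts,sleepCounts,countDispersion negative-binomial
#'   activity model: mean counts per epoch awake/asleep and dispersion
#'   (size).
#' @param epochLength seconds (default 120).
#' @param days recording length in days (default 42).
#' @param seed master seed; every stochastic draw descends from it.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(nCases = 20L, nControls = 21L,
                         tauCMean = c(case = 24 + 14 / 60,
                                      control = 24 + 13 / 60),
                         tauCSD = c(case = 12 / 60, control = 10 / 60),
                         deltaDMean = c(case = -1.82, control = 0.66),
                         deltaDSD = c(case = 1.62, control = 0.62),
                         caseProfile = availableLightProfile(160, 30),
                         controlProfile = availableLightProfile(800, 10),
                         lightJitterSD = 0.5, diaryJitterSD = 0.25,
                         luxSigma = 0.3, acrophaseOffset = 0.5,
                         acrophaseNoiseSD = 0.5, wakeCounts = 250,
                         sleepCounts = 10, countDispersion = 1.5,
                         epochLength = 120, days = 42, seed = 1L) {
  new("CohortConfig", nCases = as.integer(nCases),
      nControls = as.integer(nControls), tauCMean = tauCMean,
      tauCSD = tauCSD, deltaDMean = deltaDMean, deltaDSD = deltaDSD,
      caseProfile = caseProfile, controlProfile = controlProfile,
      lightJitterSD = lightJitterSD, diaryJitterSD = diaryJitterSD,
      luxSigma = luxSigma, acrophaseOffset = acrophaseOffset,
      acrophaseNoiseSD = acrophaseNoiseSD, wakeCounts = wakeCounts,
      sleepCounts = sleepCounts, countDispersion = countDispersion,
      epochLength = epochLength, days = days, seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d cases + %d controls, %g days of %gs epochs, seed %d\n",
    object@nCases, object@nControls, object@days, object@epochLength,
    object@seed))
})

# simulate one participant with known physiology under a light profile;
# RNG must already be seeded by the caller
.emitParticipant <- function(id, group, tauCv, deltaDv, profile, config) {
  epSec <- config@epochLength
  epH <- epSec / 3600
  lead <- 14                      # discarded conditioning days
  total <- lead + config@days
  shift <- rnorm(ceiling(total), 0, config@lightJitterSD)
  sim <- simulateModel(modelParams(tauC = tauCv, deltaD = deltaDv),
                       profile, days = total, epochLength = epSec,
                       transientDays = lead, dayShift = shift)
  w0 <- lead * 24                 # window start on the sim hour axis
  nEp <- as.integer(config@days * 24 / epH)
  iEp <- (w0 / epH) + seq_len(nEp)   # epoch indices inside the window
  origin <- .posixctOrigin()

  recLux <- sim@receivedLux[iEp] *
    exp(rnorm(nEp, 0, config@luxSigma))
  recLux[recLux < 0.1] <- 0.1     # sensor noise floor
  wake <- sim@wake[iEp]
  muA <- ifelse(wake, config@wakeCounts, config@sleepCounts)
  counts <- rnbinom(nEp, size = config@countDispersion, mu = muA)
  recording <- epochSeries(origin, counts, recLux, epochLength = epSec)

  ep <- sim@episodes
  ep <- ep[ep$onset >= w0 & ep$offset <= w0 + config@days * 24, ,
           drop = FALSE]
  onJ <- ep$onset - w0 + rnorm(nrow(ep), 0, config@diaryJitterSD)
  offJ <- ep$offset - w0 + rnorm(nrow(ep), 0, config@diaryJitterSD)
  # keep reported episodes valid and inside the recording span
  onJ <- pmax(onJ, 1 / 3600)
  offJ <- pmin(pmax(offJ, onJ + 0.5), config@days * 24 - 1 / 3600)
  onJ <- pmin(onJ, offJ - 0.25)
  if (nrow(ep) > 1) {             # resolve jitter-induced overlaps
    for (i in 2:nrow(ep)) {
      if (onJ[i] <= offJ[i - 1]) onJ[i] <- offJ[i - 1] + 1 / 60
    }
  }
  diary <- sleepEpisodes(hoursToPosix(onJ, origin),
                         hoursToPosix(offJ, origin), source = "diary")

  cw <- sim@cwpm - w0
  cw <- cw[cw >= 0 & cw <= config@days * 24]
  nWeek <- floor(config@days / 7)
  acro <- data.frame()
  if (nWeek > 0 && length(cw) > 0) {
    targets <- ((seq_len(nWeek)) - 0.5) * 7 * 24
    pick <- vapply(targets, function(tk) cw[which.min(abs(cw - tk))],
                   numeric(1))
    obs <- pick + config@acrophaseOffset +
      rnorm(nWeek, 0, config@acrophaseNoiseSD)
    acro <- data.frame(windowStart = hoursToPosix(obs - 24, origin),
                       windowEnd = hoursToPosix(obs + 24, origin),
                       acrophase = hoursToPosix(obs, origin))
  }

  record <- participantRecord(id, group, recording, diary, acro)
  truth <- data.frame(id = id, group = group, tauC = tauCv,
                      deltaD = deltaDv, LDay = profile@LDay,
                      LEve = profile@LEve,
                      meanDuration = if (nrow(ep)) {
                        mean(ep$offset - ep$onset)
                      } else NA_real_,
                      onsetPeriod = sim@onsetPeriod)
  list(record = record, truth = truth)
}

#' Generate one synthetic participant
#'
#' Draws a latent physiology (tauC, deltaD) for the requested group,
#' simulates the model in self-selected mode under the group's light
#' environment with per-day behavioral jitter, and emits a complete
#' observed dataset: a lux series (the light the model actually
#' received, degraded by multiplicative measurement noise, with a 0.1
#' lux sensor floor), negative-binomial activity counts keyed to the
#' wake/sleep state, a diary with reporting jitter, and weekly acrophase
#' records (CWPM + fixed offset + noise, each inside a 48-h collection
#' window).  The first 14 simulated days condition the state and are not
#' emitted, so the recording is in steady state from its first epoch.
#'
#' @param config a [CohortConfig-class].
#' @param group \code{"case"} or \code{"control"}.
#' @param seed integer seed for this participant (bit-identical outputs
#'   for equal seeds).
#' @param id participant identifier.
#' @return list with elements \code{record} (a
#'   [ParticipantRecord-class]) and \code{truth} (one-row data.frame of
#'   the latent values).
#' @export
generateParticipant <- function(config, group = c("case", "control"),
                                seed = config@seed, id = NULL) {
  group <- match.arg(group)
  if (is.null(id)) id <- sprintf("%s_%06d", group, seed %% 1000000L)
  .withSeed(seed, {
    for (attempt in 0:2) {
      tauCv <- .rnormTrunc(1, config@tauCMean[[group]],
                           config@tauCSD[[group]], 23.6, 25.4)
      deltaDv <- .rnormTrunc(1, config@deltaDMean[[group]],
                             config@deltaDSD[[group]], -4.5, 2.5)
      prof <- if (group == "case") config@caseProfile else
        config@controlProfile
      out <- tryCatch(
        .emitParticipant(id, group, tauCv, deltaDv, prof, config),
        error = function(e) NULL)
      if (!is.null(out)) return(out)
      message(sprintf(
        "participant %s: simulation failed, regenerating (attempt %d)",
        id, attempt + 1))
    }
    clNumericalError(sprintf("could not generate participant %s", id))
  })
}

#' Generate a full synthetic cohort
#'
#' Generates \code{nCases + nControls} participants with independent
#' sub-seeds derived from the master seed.  When \code{dir} is given,
#' writes per-participant recording/diary/acrophase CSVs (in the
#' [readRecording()]/[readDiary()]/[readAcrophases()] dialects) plus a
#' \code{ground_truth.csv}.
#'
#' @param config a [CohortConfig-class].
#' @param dir optional output directory.
#' @return list with \code{participants} (list of
#'   [ParticipantRecord-class]) and \code{truth} (data.frame, one row
#'   per participant).
#' @export
generateCohort <- function(config, dir = NULL) {
  ids <- c(sprintf("case%02d", seq_len(config@nCases)),
           sprintf("ctrl%02d", seq_len(config@nControls)))
  groups <- rep(c("case", "control"), c(config@nCases, config@nControls))
  subSeed <- (as.numeric(config@seed) * 10007 + seq_along(ids)) %%
    2147483647
  out <- lapply(seq_along(ids), function(i) {
    generateParticipant(config, groups[i], seed = as.integer(subSeed[i]),
                        id = ids[i])
  })
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  participants <- lapply(out, `[[`, "record")
  names(participants) <- ids
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in participants) {
      writeRecording(p@recording, file.path(dir,
                                            paste0(p@id, "_recording.csv")))
      writeDiary(p@episodes, file.path(dir, paste0(p@id, "_diary.csv")))
      if (nrow(p@acrophases))
        writeAcrophases(p@acrophases,
                        file.path(dir, paste0(p@id, "_acrophase.csv")))
    }
    write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  list(participants = participants, truth = truth)
}

#' Paired winter/summer records for one physiology
#'
#' An in-silico natural experiment: one latent physiology (default a
#' long intrinsic period with a strongly reduced wake drive) is
#' simulated under a dim winter availability profile and again under a
#' bright summer profile.  Only the light differs between the two
#' records; under the dim winter profile the sleep-wake rhythm
#' free-runs (dominant activity period above 24 h) while the bright
#' summer profile restores a 24-h rhythm.
#'
#' @param seed integer seed.
#' @param tauCv,deltaDv the shared physiology (defaults 24.25 h and
#'   -1.8).
#' @param winterProfile,summerProfile the two light environments
#'   (defaults: dim winter 160/30 lux, bright summer 1500/10 lux).
#' @param config a [CohortConfig-class] supplying noise levels and
#'   recording geometry.
#' @return list with [ParticipantRecord-class] elements \code{winter}
#'   and \code{summer} and a \code{truth} data.frame (identical
#'   physiology in both rows).
#' @export
seasonalScenario <- function(seed = 1L, tauCv = 24.25, deltaDv = -1.8,
                             winterProfile = availableLightProfile(160, 30),
                             summerProfile = availableLightProfile(1500, 10),
                             config = cohortConfig(seed = seed)) {
  winter <- .withSeed(seed, .emitParticipant("sz01wi", "case", tauCv,
                                             deltaDv, winterProfile,
                                             config))
  summer <- .withSeed(seed + 1L, .emitParticipant("sz01su", "case", tauCv,
                                                  deltaDv, summerProfile,
                                                  config))
  list(winter = winter$record, summer = summer$record,
       truth = rbind(winter$truth, summer$truth))
}
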