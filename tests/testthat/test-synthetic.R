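test_that("generation is bit-identical for equal seeds", {
  cfg <- cohortConfig(days = 28, seed = 2)
  a <- generateParticipant(cfg, "case", seed = 17)
  b <- generateParticipant(cfg, "case", seed = 17)
  expect_identical(luxValues(a$record@recording),
                   luxValues(b$record@recording))
  expect_identical(activityCounts(a$record@recording),
                   activityCounts(b$record@recording))
  expect_identical(episodeTable(a$record@episodes),
                   episodeTable(b$record@episodes))
  expect_identical(a$truth, b$truth)
  c <- generateParticipant(cfg, "case", seed = 18)
  expect_false(identical(luxValues(a$record@recording),
                         luxValues(c$record@recording)))
})

test_that("emitted datasets satisfy the domain invariants", {
  pp <- fxControlParticipant()
  rec <- pp$record@recording
  expect_true(all(luxValues(rec) >= 0.1))     # sensor floor
  expect_true(all(activityCounts(rec) >= 0))
  expect_true(validObject(pp$record))
  acro <- pp$record@acrophases
  expect_equal(nrow(acro), 6)                 # weekly over 42 days
  expect_true(all(acro$acrophase >= acro$windowStart &
                    acro$acrophase <= acro$windowEnd))
  tab <- episodeTable(pp$record@episodes)
  expect_true(all(tab$duration > 0 & tab$duration < 24))
})

test_that("a bright-environment control sleeps regularly on a 24-h day", {
  pp <- fxControlParticipant()
  scan <- foldPeriodScan(pp$record@recording)
  expect_lte(abs(scan@dominantPeriod - 24), 2 / 60 + 1e-9)
  s <- sleepTimingSummary(pp$record@episodes)
  expect_true(s$durationMean > 6 && s$durationMean < 9.5)
})

test_that("a dim-environment low-drive case free-runs with long sleep", {
  cfg <- cohortConfig(seed = 6)
  pp <- .withSeedLocal(6, circalight:::.emitParticipant(
    "sz", "case", 24.6, -1.8, availableLightProfile(160, 30), cfg))
  scan <- foldPeriodScan(pp$record@recording)
  expect_gt(scan@dominantPeriod, 24.2)
  s <- sleepTimingSummary(pp$record@episodes)
  expect_gt(s$durationMean, 9)
  # onsets drift: large circular spread
  expect_gt(s$onset@circularSD, 1)
})

test_that("tauC draws depend only on the sub-seed, not the group label", {
  cfg <- cohortConfig(nCases = 3, nControls = 3,
                      tauCMean = c(case = 24.2, control = 24.2),
                      tauCSD = c(case = 0.15, control = 0.15),
                      days = 28, seed = 9)
  a <- generateCohort(cfg)
  # tauC is the first draw from each sub-seed, so permuting group labels
  # across positions leaves the pooled tauC distribution untouched
  cfgPerm <- cohortConfig(nCases = 0, nControls = 6,
                          tauCMean = c(case = 24.2, control = 24.2),
                          tauCSD = c(case = 0.15, control = 0.15),
                          days = 28, seed = 9)
  expect_silent(p <- generateCohort(cfgPerm))
  expect_equal(sort(p$truth$tauC), sort(a$truth$tauC), tolerance = 1e-12)
})

test_that("the seasonal scenario changes light only, not physiology", {
  ss <- fxMemo("seasonal", seasonalScenario(seed = 3))
  expect_equal(ss$truth$tauC[1], ss$truth$tauC[2])
  expect_equal(ss$truth$deltaD[1], ss$truth$deltaD[2])
  expect_gt(lightMetrics(ss$summer@recording)@medianBrightHours,
            lightMetrics(ss$winter@recording)@medianBrightHours)
})

test_that("cohort files written to disk re-read as a valid dataset", {
  cfg <- cohortConfig(nCases = 1, nControls = 1, days = 28, seed = 13)
  dirf <- withr::local_tempdir()
  coh <- generateCohort(cfg, dir = dirf)
  files <- list.files(dirf)
  expect_true("ground_truth.csv" %in% files)
  expect_length(grep("_recording.csv$", files), 2)
  rec <- readRecording(file.path(dirf, "case01_recording.csv"))
  expect_equal(nEpochs(rec),
               nEpochs(coh$participants[["case01"]]@recording))
  diary <- readDiary(file.path(dirf, "case01_diary.csv"))
  expect_equal(nEpisodes(diary),
               nEpisodes(coh$participants[["case01"]]@episodes))
  truth <- read.csv(file.path(dirf, "ground_truth.csv"))
  expect_equal(nrow(truth), 2)
  expect_true(all(c("tauC", "deltaD") %in% names(truth)))
})
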