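test_that("diary episodes roll offsets across midnight and keep same-day rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,onset_time,offset_time",
               "2024-01-01,23:30,07:30",
               "2024-01-03,02:00,11:00"), f)
  ep <- readDiary(f)
  tab <- episodeTable(ep)
  expect_equal(nEpisodes(ep), 2)
  expect_equal(tab$duration, c(8, 9))
  expect_equal(format(tab$offset[1], "%Y-%m-%d %H:%M", tz = "UTC"),
               "2024-01-02 07:30")
  expect_equal(format(tab$onset[2], "%Y-%m-%d", tz = "UTC"), "2024-01-03")
})

test_that("diary read preserves episode count and order on a long diary", {
  dates <- format(as.Date("2024-01-01") + 0:41)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,onset_time,offset_time",
               paste(dates, "23:15", "07:05", sep = ",")), f)
  ep <- readDiary(f)
  expect_equal(nEpisodes(ep), 42)
  expect_false(is.unsorted(as.numeric(ep@onset)))
})

test_that("overlapping diary episodes raise a data error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,onset_time,offset_time",
               "2024-01-01,22:00,09:00",
               "2024-01-02,08:00,16:00"), f)
  expect_error(readDiary(f), class = "circalight_data_error")
})

test_that("recording round-trips through the CSV dialect, including gaps", {
  n <- 720 * 2
  act <- rpois(n, 50)
  lux <- runif(n, 0, 900)
  miss <- rep(FALSE, n)
  miss[101:105] <- TRUE  # one 10-min gap
  es <- epochSeries("2024-03-01", act, lux, missing = miss)
  f <- withr::local_tempfile(fileext = ".csv")
  writeRecording(es, f)
  es2 <- readRecording(f)
  expect_equal(nEpochs(es2), n)
  expect_equal(missingMask(es2), miss)
  expect_equal(activityCounts(es2)[!miss], act[!miss], tolerance = 1e-8)
  expect_equal(luxValues(es2)[!miss], lux[!miss], tolerance = 1e-6)
  expect_equal(as.numeric(startTime(es2)), as.numeric(startTime(es)))
})

test_that("recording reader rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,activity,lux",
               "2024-01-01T00:00:00,1,0",
               "2024-01-01T00:02:00,2,0"), f)
  expect_error(readRecording(f), class = "circalight_insufficient_data_error")

  writeLines(c("timestamp,activity,lux",
               "not-a-time,1,0",
               "2024-01-02T00:02:00,2,0"), f)
  expect_error(readRecording(f), class = "circalight_format_error")

  long <- format(seq(as.POSIXct("2024-01-01", tz = "UTC"), by = 120,
                     length.out = 800), "%Y-%m-%dT%H:%M:%S")
  writeLines(c("timestamp,activity,lux",
               paste(c(long, long[1]), 1, 0, sep = ",")), f)
  expect_error(readRecording(f), class = "circalight_data_error")
})

test_that("epoch series invariants are enforced", {
  expect_error(epochSeries("2024-01-01", -1, 5), "activity")
  expect_error(epochSeries("2024-01-01", c(1, 2), c(5, 5),
                           epochLength = 700), "divide")
  expect_error(sleepEpisodes("2024-01-01 23:00", "2024-01-01 22:00"),
               "offset")
  expect_error(sleepEpisodes(c("2024-01-01 20:00", "2024-01-02 02:00"),
                             c("2024-01-02 04:00", "2024-01-02 10:00")),
               "overlap")
})

test_that("acrophase records round-trip and enforce the window invariant", {
  acro <- data.frame(
    windowStart = as.POSIXct("2024-01-07 00:00", tz = "UTC"),
    windowEnd = as.POSIXct("2024-01-09 00:00", tz = "UTC"),
    acrophase = as.POSIXct("2024-01-08 04:30", tz = "UTC"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeAcrophases(acro, f)
  back <- readAcrophases(f)
  expect_equal(as.numeric(back$acrophase), as.numeric(acro$acrophase))

  bad <- acro
  bad$acrophase <- bad$windowEnd + 3600
  writeAcrophases(bad, f)
  expect_error(readAcrophases(f), class = "circalight_data_error")
})

test_that("synthetic cohort output re-reads identically", {
  pp <- fxControlParticipant()
  dirf <- withr::local_tempdir()
  writeRecording(pp$record@recording, file.path(dirf, "r.csv"))
  writeDiary(pp$record@episodes, file.path(dirf, "d.csv"))
  r2 <- readRecording(file.path(dirf, "r.csv"))
  expect_equal(luxValues(r2), luxValues(pp$record@recording),
               tolerance = 1e-6)
  expect_equal(activityCounts(r2), activityCounts(pp$record@recording))
  d2 <- readDiary(file.path(dirf, "d.csv"))
  expect_equal(nEpisodes(d2), nEpisodes(pp$record@episodes))
  # diary written at whole-second precision
  expect_lt(max(abs(as.numeric(d2@onset) -
                      as.numeric(pp$record@episodes@onset))), 1)
})
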