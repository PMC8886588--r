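test_that("folding recovers an exact 24-h square wave with near-zero residual", {
  es <- makeSquareSeries(24, days = 42)
  scan <- foldPeriodScan(es)
  expect_equal(scan@dominantPeriod, 24)
  expect_lt(min(scan@residualVariance), 1e-10)
  expect_true(all(scan@residualVariance >= 0 & scan@residualVariance <= 1))
})

test_that("folding recovers a noisy imposed non-24-h period within one grid step", {
  es <- makeSquareSeries(24 + 38 / 60, days = 42, noiseSD = 50, seed = 3)
  scan <- foldPeriodScan(es)
  expect_lte(abs(scan@dominantPeriod - (24 + 38 / 60)), 2 / 60 + 1e-9)
})

test_that("white noise yields a flat scan with depth near one", {
  n <- 42 * 720
  es <- .withSeedLocal(9, epochSeries("2024-01-01", rnorm(n, 100, 10),
                                      rep(0, n)))
  scan <- foldPeriodScan(es)
  expect_gt(scan@depth, 0.95)
  expect_gt(min(scan@residualVariance), 0.9)
})

test_that("the residual-variance profile is invariant under affine transforms", {
  es <- makeSquareSeries(24.5, days = 30, noiseSD = 30, seed = 4)
  a <- foldPeriodScan(es)
  es2 <- epochSeries(startTime(es), 3.7 * activityCounts(es) + 55,
                     luxValues(es), epochLength = epochLength(es))
  b <- foldPeriodScan(es2)
  expect_equal(a@residualVariance, b@residualVariance, tolerance = 1e-9)
  expect_equal(a@dominantPeriod, b@dominantPeriod)
})

test_that("folding matches a brute-force least-squares periodic fit", {
  # small instance: 3 days at 10-min resolution
  for (P in c(22.5, 24, 25.5)) {
    es <- makeSquareSeries(P, days = 9, epochSec = 600, noiseSD = 40,
                           seed = round(P * 10))
    cand <- seq(21, 27, by = 1 / 6)
    scan <- foldPeriodScan(es, periodRange = c(21, 27))
    x <- activityCounts(es)
    tH <- (seq_along(x) - 1) / 6
    oracle <- bruteForcePeriodFit(x, tH, cand, 1 / 6)
    expect_equal(scan@dominantPeriod, oracle, tolerance = 1e-9)
  }
})

test_that("degenerate and out-of-range folding inputs are rejected", {
  esConst <- epochSeries("2024-01-01", rep(5, 720 * 7), rep(0, 720 * 7))
  expect_error(foldPeriodScan(esConst),
               class = "circalight_degenerate_signal_error")
  es <- makeSquareSeries(24, days = 7)
  expect_error(foldPeriodScan(es, periodRange = c(20, 60)),
               class = "circalight_range_error")
})

test_that("circular mean respects wrap-around and degenerate cases", {
  expect_equal(circularTimeStats(c(23.5, 0.5))@meanTime, 0)
  s <- circularTimeStats(c(8, 8, 8))
  expect_equal(s@meanTime, 8)
  expect_equal(s@circularVariance, 0)
  expect_equal(s@circularSD, 0)
  # antipodal times: resultant length zero, flagged not an error
  u <- circularTimeStats(c(3, 15))
  expect_true("undefined_mean" %in% u@flags)
  expect_true(is.na(u@meanTime))
  expect_error(circularTimeStats(5),
               class = "circalight_insufficient_data_error")
})

test_that("uniform times give near-zero resultant length", {
  h <- .withSeedLocal(10, runif(10000, 0, 24))
  s <- circularTimeStats(h)
  expect_lt(s@resultantLength, 0.03)
})

test_that("circular and linear means agree for tightly clustered times", {
  h <- .withSeedLocal(11, runif(200, 10.5, 13.5))  # tight 3-h arc
  s <- circularTimeStats(h)
  expect_lt(abs(s@meanTime - mean(h)), 1 / 60)
})

test_that("circular SD matches the closed form for a two-point distribution", {
  h <- rep(c(22, 2), 21)
  s <- circularTimeStats(h)
  expect_equal(s@meanTime, 0)
  # R = |cos(delta/2 * 2pi/24)| for times +/- delta/2 around the mean
  R <- cos(2 * (2 * pi / 24))
  expect_equal(s@resultantLength, R, tolerance = 1e-12)
  expect_equal(s@circularSD, 24 / (2 * pi) * sqrt(-2 * log(R)),
               tolerance = 1e-12)
})

test_that("sleep timing summary reduces correctly for a metronomic sleeper", {
  on <- as.POSIXct("2024-01-01 23:00", tz = "UTC") + (0:41) * 86400
  ep <- sleepEpisodes(on, on + 8 * 3600)
  s <- sleepTimingSummary(ep)
  expect_equal(s$durationMean, 8)
  expect_equal(s$durationSD, 0)
  expect_equal(s$offset@circularVariance, 0)
  expect_equal(s$midSleep@meanTime, 3)
  expect_error(sleepTimingSummary(sleepEpisodes(on[1], on[1] + 3600)),
               class = "circalight_insufficient_data_error")
})

test_that("light metrics match hand computations and the strict threshold", {
  n <- 720 * 10
  es600 <- epochSeries("2024-01-01", rep(0, n), rep(600, n))
  expect_equal(lightMetrics(es600)@medianBrightHours, 24)
  es499 <- epochSeries("2024-01-01", rep(0, n), rep(499, n))
  expect_equal(lightMetrics(es499)@medianBrightHours, 0)
  # 12 h at 1000 lux, 12 h dark
  esHalf <- epochSeries("2024-01-01", rep(0, n),
                        rep(rep(c(1000, 0), each = 360), 10))
  lm <- lightMetrics(esHalf)
  expect_equal(lm@medianBrightHours, 12)
  expect_equal(lm@medianDailyLux, 500)
  expect_equal(lm@medianDailyLogLux, 0.5 * log(1001), tolerance = 1e-12)
})

test_that("adding light never decreases any light metric", {
  pp <- fxControlParticipant()
  es <- pp$record@recording
  before <- lightMetrics(es)
  lx <- luxValues(es)
  idx <- .withSeedLocal(12, sample(length(lx), 2000))
  lx[idx] <- lx[idx] + 800
  es2 <- epochSeries(startTime(es), activityCounts(es), lx,
                     epochLength = epochLength(es))
  after <- lightMetrics(es2)
  expect_gte(after@medianBrightHours, before@medianBrightHours)
  expect_gte(after@medianDailyLux, before@medianDailyLux)
  expect_gte(after@medianDailyLogLux, before@medianDailyLogLux)
})

test_that("fully masked recordings are rejected by light metrics", {
  n <- 720 * 8
  es <- epochSeries("2024-01-01", rep(1, n), rep(1, n),
                    missing = rep(TRUE, n))
  expect_error(lightMetrics(es),
               class = "circalight_insufficient_data_error")
})
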