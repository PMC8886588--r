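test_that("noise-free self-consistency: the fit returns the generating values", {
  nf <- fxNoiseFreeParticipant()
  fit <- fitParticipant(nf$record)
  expect_lt(abs(fit@tauCHat - 24.2), 0.05)
  expect_lt(abs(fit@deltaDHat - 0), 0.15)
  expect_lt(fit@objective, 0.01)
})

test_that("the objective's global minimum sits at the generating parameters", {
  # brute-force oracle: exhaustive evaluation over a local grid around
  # the truth on noise-free data
  nf <- fxNoiseFreeParticipant()
  rec <- nf$record@recording
  tab <- episodeTable(nf$record@episodes)
  origin <- startTime(rec)
  post <- (as.numeric(tab$onset) - as.numeric(origin)) / 3600 >= 14 * 24
  obsMid <- circalight:::circMeanHours(
    (as.numeric(tab$midSleep[post]) %% 86400) / 3600)
  obsDur <- mean(tab$duration[post])
  grid <- expand.grid(tauC = seq(23.8, 24.6, by = 0.1),
                      deltaD = seq(-1, 1, by = 0.25))
  cache <- new.env(parent = emptyenv())
  grid$J <- mapply(function(tc, dd)
    circalight:::.fitEval(tc, dd, rec, obsMid, obsDur, 14, cache)$J,
    grid$tauC, grid$deltaD)
  best <- grid[which.min(grid$J), ]
  expect_equal(best$tauC, 24.2, tolerance = 1e-9)
  expect_equal(best$deltaD, 0, tolerance = 1e-9)
})

test_that("fits of noisy participants recover the truth and flag basins", {
  pp <- fxControlParticipant()
  fit <- fitParticipant(pp$record)
  expect_lt(abs(fit@tauCHat - pp$truth$tauC), 0.1)
  expect_lt(abs(fit@deltaDHat - pp$truth$deltaD), 0.2)
  expect_false("boundary" %in% fit@flags)
  expect_s4_class(fit, "FitResult")
  expect_true(is.data.frame(fit@convergence$coarse))
})

test_that("fitting requires enough episodes", {
  pp <- fxControlParticipant()
  short <- pp$record
  keep <- 1:10
  short@episodes <- sleepEpisodes(short@episodes@onset[keep],
                                  short@episodes@offset[keep])
  expect_error(fitParticipant(short),
               class = "circalight_insufficient_data_error")
})

test_that("acrophase prediction is the CWPM shifted by the offset", {
  sim <- fxDefaultSim()
  pred0 <- predictAcrophase(sim, offset = 0)
  expect_equal((as.numeric(pred0) - as.numeric(sim@origin)) / 3600,
               cwpmTimes(sim), tolerance = 1e-9)
  pred <- predictAcrophase(sim, offset = 0.5)
  expect_equal(as.numeric(pred) - as.numeric(pred0), rep(1800, length(pred)))
  # entrained simulation: predicted acrophases recur every 24 h
  expect_equal(diff(as.numeric(pred)) / 3600, rep(24, length(pred) - 1),
               tolerance = 0.1)
})

test_that("the CWPM-to-acrophase offset is recoverable from synthetic records", {
  pp <- fxControlParticipant()
  sim <- simulateModel(modelParams(tauC = pp$truth$tauC,
                                   deltaD = pp$truth$deltaD),
                       pp$record@recording, transientDays = 0)
  cal <- calibrateAcrophaseOffset(sim, pp$record@acrophases)
  # generator builds acrophases as CWPM + 0.5 h + noise (SD 0.5 h, n = 6)
  expect_lt(abs(cal - 0.5), 0.7)
})

test_that("acrophase validation summarizes agreement correctly", {
  # pooled predictions across three drifting phases so clock times vary
  base <- as.POSIXct("2024-01-05 04:00", tz = "UTC")
  pred <- base + c(0:5 * 24.6, 200 + 0:5 * 25.2, 420 + 0:5 * 23.4) * 3600
  acro <- data.frame(windowStart = pred - 12 * 3600,
                     windowEnd = pred + 12 * 3600, acrophase = pred)
  v <- validateAcrophase(pred, acro)
  expect_equal(v$n, length(pred))
  expect_equal(v$correlation, 1, tolerance = 1e-9)
  expect_equal(v$rmse, 0)
  expect_equal(v$slope, 1, tolerance = 1e-9)

  noisy <- acro
  noise <- .withSeedLocal(31, rnorm(length(pred), 0, 0.5))
  noisy$acrophase <- noisy$acrophase + noise * 3600
  noisy$windowStart <- noisy$acrophase - 12 * 3600
  noisy$windowEnd <- noisy$acrophase + 12 * 3600
  v2 <- validateAcrophase(pred, noisy)
  expect_equal(v2$rmse, 0.5, tolerance = 0.25)

  shuffled <- acro
  shuffled$acrophase <- shuffled$acrophase +
    .withSeedLocal(32, sample(c(-9, -5, 5, 9), length(pred), TRUE)) * 3600
  shuffled$windowStart <- shuffled$acrophase - 12 * 3600
  shuffled$windowEnd <- shuffled$acrophase + 12 * 3600
  v3 <- validateAcrophase(pred, shuffled)
  expect_lt(abs(v3$correlation), 0.5)

  expect_error(validateAcrophase(pred[1:2], acro[1:2, ]),
               class = "circalight_insufficient_data_error")
})
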