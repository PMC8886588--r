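# Shared fixtures, memoized so expensive simulations run once per suite.

.fx <- new.env(parent = emptyenv())

fxMemo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# square-wave activity recording with an imposed period and additive
# Gaussian noise; SNR = (amplitude/2) / noiseSD
makeSquareSeries <- function(periodH, days = 42, epochSec = 120,
                             noiseSD = 0, seed = 1, amplitude = 100) {
  n <- days * 24 * 3600 / epochSec
  tH <- (seq_len(n) - 1) * epochSec / 3600
  x <- amplitude * as.numeric((tH %% periodH) < periodH / 2)
  if (noiseSD > 0) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    x <- x + rnorm(n, 0, noiseSD)
  }
  x <- pmax(x, 0)
  epochSeries("2024-01-01", activity = x, lux = rep(0, n),
              epochLength = epochSec)
}

# brute-force least-squares periodic-waveform fit: for each candidate
# period, model the signal as an arbitrary waveform constant within
# phase bins and pick the period minimizing the residual sum of squares.
# Written naively (explicit loop, tapply means) as an independent oracle
# for foldPeriodScan.
bruteForcePeriodFit <- function(x, tH, candidates, binH) {
  sse <- sapply(candidates, function(P) {
    bin <- factor(floor((tH %% P) / binH))
    fitted <- ave(x, bin)
    sum((x - fitted)^2)
  })
  candidates[which.min(sse)]
}

# default entrained simulation under the bright reference routine
fxDefaultSim <- function() fxMemo("defaultSim", {
  simulateModel(modelParams(), availableLightProfile(1000, 10), days = 30)
})

# one noisy control-like participant (used by fitting and metric tests)
fxControlParticipant <- function() fxMemo("ctrlPart", {
  generateParticipant(cohortConfig(seed = 42), "control", seed = 42)
})

# noise-free participant at known parameters for self-consistency tests
fxNoiseFreeParticipant <- function() fxMemo("nfPart", {
  cfg <- cohortConfig(lightJitterSD = 0, diaryJitterSD = 0, luxSigma = 0,
                      acrophaseNoiseSD = 0, seed = 5)
  .withSeedLocal(5, circalight:::.emitParticipant(
    "nf01", "control", 24.2, 0, availableLightProfile(800, 10), cfg))
})

.withSeedLocal <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# small entrainment map for a late-phase, low-wake-drive individual
# (paper-like physiology); reused by intervention and acceptance tests
fxSmallMap <- function() fxMemo("smallMap", {
  entrainmentMap(modelParams(tauC = 24.17, deltaD = -1.73),
                 c(160, 300, 450, 795, 1200), c(3, 7, 20, 30), days = 70)
})

# synthetic cohort at default group sizes
fxCohort <- function() fxMemo("cohort", {
  generateCohort(cohortConfig(seed = 11))
})

# recovery study: 20 participants with default noise
fxRecovery <- function() fxMemo("recovery", {
  cfg <- cohortConfig(nCases = 10, nControls = 10, seed = 7)
  coh <- generateCohort(cfg)
  fits <- lapply(coh$participants, fitParticipant)
  list(truth = coh$truth, fits = fits)
})
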