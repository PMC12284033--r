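mkIntervalSet <- function(onRanges, nFrames = 100, dt = 0.1,
                          spot = "s1", experiment = "e1") {
  binarizeTrace(squareTrace(nFrames, onRanges, dt = dt), experiment =
                  experiment) -> iv
  iv@spotId <- spot
  iv
}

test_that("dwell collection pools uncensored on-intervals only", {
  iv <- mkIntervalSet(list(c(21, 25), c(51, 62)))
  d <- collectDwells(list(iv))
  expect_equal(sort(durations(d)), c(0.5, 1.2))

  ## a movie-spanning on interval is fully censored
  allOn <- binarizeTrace(trace(rep(100, 50), 0.1), onLevelPrior = 100)
  expect_error(collectDwells(list(allOn)), "no uncensored")
  ## but can be retained explicitly, flagged
  dc <- collectDwells(list(allOn), includeCensored = TRUE)
  expect_true(all(dc@censored))

  ## collected dwell count equals the simulator's completed events
  cfg <- simConfig(
    imaging = imagingModel(fieldEdge = 32, readNoiseSd = 2),
    kinetics = kineticsConfig(kOff = 0.6, kOnPseudo = 0.2, bleachRate = 0),
    discDensity = 1, binderOccupancy = 1, nonspecificDensity = 0,
    nFrames = 250, minSeparation = 0, rngSeed = 33)
  f <- simulateField(cfg, channels = "protein")
  p <- f$truth@discPositions
  if (p$x[1] > 8 && p$x[1] < 24 && p$y[1] > 8 && p$y[1] < 24) {
    iv <- binarizeTrace(extractTrace(f$protein, p$x[1], p$y[1]))
    bi <- f$truth@bindingIntervals
    complete <- sum(bi$start > 0 & bi$end < f$truth@movieLength)
    gaps <- diff(bi[order(bi$start), ]$start)
    if (all(bi$end - bi$start > 0.12) && all(gaps > 0.25)) {
      d <- collectDwells(list(iv))
      expect_equal(length(durations(d)), complete)
    }
  }
})

test_that("the exponential MLE matches its closed forms and invariants", {
  f <- fitExponentialMLE(dwellTimeSet(c(1, 2, 3)))
  expect_equal(kOff(f), 0.5)
  expect_equal(f@se, 0.5 / sqrt(3))
  expect_equal(f@logLik, 3 * log(0.5) - 0.5 * 6)

  ## n identical durations t give rate 1/t
  f2 <- fitExponentialMLE(dwellTimeSet(rep(0.4, 50)))
  expect_equal(kOff(f2), 2.5)

  ## CI contains the estimate; log-Wald form
  expect_true(f@ci95[1] < kOff(f) && kOff(f) < f@ci95[2])
  expect_equal(f@ci95, 0.5 * exp(c(-1, 1) * qnorm(0.975) / sqrt(3)))

  expect_error(fitExponentialMLE(dwellTimeSet(1)), "at least 2")
})

test_that("the closed form equals the grid-search likelihood argmax", {
  set.seed(10)
  for (i in 1:10) {
    durs <- rexp(sample(5:30, 1), rexp(1, 0.5) + 0.05)
    f <- fitExponentialMLE(dwellTimeSet(durs))
    expect_equal(kOff(f), gridSearchRate(durs), tolerance = 1e-6)
  }
})

test_that("frame-discretized fits remove the ceiling bias", {
  d <- simulateDwellTimes(0.55, 20000, frameInterval = 0.1, rngSeed = 12)
  corrected <- fitExponentialMLE(d)
  naive <- fitExponentialMLE(d, discretization = "none")
  expect_equal(kOff(corrected), 0.55, tolerance = 0.02)
  ## the naive closed form on ceiling-discretized data is biased low,
  ## by about k*dt/2, but stays within the documented 5% at k*dt = 0.055
  expect_lt(kOff(naive), kOff(corrected))
  expect_equal(kOff(naive), 0.55, tolerance = 0.05)
  expect_equal(corrected@method, "frame-discretized")
})

test_that("the likelihood-ratio test matches the closed form and is
          symmetric", {
  A <- dwellTimeSet(rep(2, 100))  # n = 100, sum = 200
  B <- dwellTimeSet(rep(1, 100))  # n = 100, sum = 100
  r <- lrtCompare(A, B)
  oracle <- 2 * (expLogLikAtMLE(100, 200) + expLogLikAtMLE(100, 100) -
                   expLogLikAtMLE(200, 300))
  expect_equal(r@statistic, oracle)
  expect_equal(r@statistic, 23.56, tolerance = 0.001)
  expect_equal(r@pValue, 1.2e-6, tolerance = 0.02)

  ## symmetry and the identical-set null
  expect_equal(lrtCompare(B, A)@statistic, r@statistic)
  same <- lrtCompare(A, A)
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)

  expect_error(lrtCompare(dwellTimeSet(1.5), A), "at least 2")
})

test_that("rebinding is two or more bound intervals per spot", {
  ivs <- list(mkIntervalSet(list(c(11, 15))),
              mkIntervalSet(list(c(11, 15))),
              mkIntervalSet(list(c(11, 15), c(41, 44))),
              mkIntervalSet(list(c(21, 28))))
  r <- rebindingFraction(ivs)
  expect_equal(r@percent, 25)
  expect_equal(r@nSpots, 4L)

  none <- rebindingFraction(ivs[1:2])
  expect_equal(none@percent, 0)

  ## per-experiment summaries and the two-condition comparison
  mk <- function(expt, rebind) mkIntervalSet(
    if (rebind) list(c(11, 15), c(41, 44)) else list(c(11, 15)),
    experiment = expt)
  a <- rebindingFraction(c(lapply(c("e1", "e1", "e2"), mk, rebind = TRUE),
                           lapply(c("e1", "e2", "e2"), mk, rebind = FALSE)))
  expect_equal(a@perExperiment$percent,
               c(100 * 2 / 3, 100 * 1 / 3))
  b <- rebindingFraction(lapply(rep(c("e1", "e2"), each = 3), mk,
                                rebind = FALSE))
  tt <- compareRebinding(a, b)
  expect_s3_class(tt, "htest")
  expect_equal(unname(tt$estimate[2]), 0)
})

test_that("simulated rebinding frequency matches the renewal expectation", {
  ## with kOff >> kOnPseudo the binding starts are nearly Poisson(kOn * T),
  ## so among spots that bind at least once the rebinding fraction is
  ## P(N >= 2 | N >= 1); kOn is chosen so that expectation is ~30%
  kOn <- 0.0227; Tm <- 30; kOffHigh <- 4
  nEvents <- vapply(1:800, function(i) {
    cfg <- simConfig(imaging = imagingModel(fieldEdge = 16),
                     kinetics = kineticsConfig(kOff = kOffHigh,
                                               kOnPseudo = kOn,
                                               bleachRate = 0),
                     discDensity = 1, binderOccupancy = 1,
                     nonspecificDensity = 0, nFrames = Tm * 10,
                     minSeparation = 0, rngSeed = 5000 + i)
    nrow(simulateField(cfg, channels = character(0))$truth@bindingIntervals)
  }, integer(1))
  lam <- kOn * Tm
  pRebind <- (1 - exp(-lam) * (1 + lam)) / (1 - exp(-lam))  # ~0.30
  observed <- sum(nEvents >= 2) / sum(nEvents >= 1)
  expect_equal(observed, pRebind, tolerance = 0.12)
})
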