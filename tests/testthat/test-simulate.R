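test_that("dwell-time draws follow the exponential law and the frame floor", {
  d <- simulateDwellTimes(0.5, 100000, frameInterval = 0, rngSeed = 1)
  expect_equal(mean(durations(d)), 2.0, tolerance = 0.01)

  ## determinism: identical seed, identical draws
  a <- simulateDwellTimes(0.7, 500, frameInterval = 0.1, rngSeed = 42)
  b <- simulateDwellTimes(0.7, 500, frameInterval = 0.1, rngSeed = 42)
  expect_identical(durations(a), durations(b))

  ## discretization floor: no duration below one frame, all whole frames
  expect_true(all(durations(a) >= 0.1 - 1e-12))
  expect_true(all(abs(durations(a) / 0.1 - round(durations(a) / 0.1)) <
                    1e-9))
  expect_error(simulateDwellTimes(0, 10), "kOff")
})

test_that("bleach traces are descending staircases with known truth", {
  tr1 <- simulateBleachTrace(1, 0.3, levelPerFluor = 80, nFrames = 100,
                             noiseSd = 0, rngSeed = 3)
  y <- intensity(tr1)
  drops <- which(diff(y) != 0)
  expect_length(drops, tr1@metadata$visibleSteps)
  if (tr1@metadata$visibleSteps == 1) {
    expect_equal(unique(y[(drops[1] + 1):length(y)]), 0)
    expect_equal(unique(y[1:drops[1]]), 80)
  }

  ## two fluorophores with equal level: two equal-height drops
  tr2 <- simulateBleachTrace(2, 0.3, levelPerFluor = 80, nFrames = 200,
                             noiseSd = 0, rngSeed = 11)
  if (tr2@metadata$visibleSteps == 2) {
    d <- diff(intensity(tr2))
    expect_equal(sort(unique(d[d != 0])), -80)
  }
  expect_error(simulateBleachTrace(5, 0.3), "nFluors")

  ## expected observed steps matches the analytic completion probability
  rate <- 0.05; Tmov <- 20; nFr <- 200
  obs <- vapply(1:400, function(i)
    simulateBleachTrace(3, rate, nFrames = nFr, rngSeed = 500 + i
                        )@metadata$visibleSteps, integer(1))
  expect_equal(mean(obs), 3 * (1 - exp(-rate * Tmov)), tolerance = 0.05)
})

test_that("simulated fields honour density, occupancy and determinism", {
  cfg <- smallFieldConfig(seed = 9, nDiscs = 40)
  f <- simulateField(cfg)
  expect_equal(nrow(f$truth@discPositions), 40)
  expect_s4_class(f$disc, "MovieStack")
  expect_equal(nFrames(f$disc), 20)

  ## identical seed => identical frames and truth
  g <- simulateField(cfg)
  expect_identical(frames(f$disc), frames(g$disc))
  expect_identical(f$truth@bindingIntervals, g$truth@bindingIntervals)

  ## zero density: pure noise, empty truth
  f0 <- simulateField(smallFieldConfig(seed = 1, nDiscs = 0))
  expect_equal(nrow(f0$truth@discPositions), 0)
  expect_lt(max(abs(frames(f0$disc) - 100)) / 8, 6)  # offset +/- read noise

  ## impossible packing is refused
  expect_error(
    simulateField(simConfig(imaging = imagingModel(fieldEdge = 16),
                            discDensity = 500, rngSeed = 1)),
    "field too small")
})

test_that("stable binders with no bleaching give constant protein traces", {
  cfg <- simConfig(
    imaging = imagingModel(fieldEdge = 64, readNoiseSd = 0,
                           shotNoise = FALSE),
    kinetics = kineticsConfig(kOnPseudo = 0, stableFraction = 1,
                              bleachRate = 0),
    discDensity = 6, binderOccupancy = 1, nonspecificDensity = 0,
    nFrames = 40, rngSeed = 5)
  f <- simulateField(cfg)
  arr <- frames(f$protein)
  perFrame <- apply(arr, 3, sum)
  expect_equal(max(perFrame) - min(perFrame), 0, tolerance = 1e-8)
})

test_that("noise-free aperture sums recover the injected photon count", {
  cfg <- simConfig(
    imaging = imagingModel(fieldEdge = 48, readNoiseSd = 0,
                           shotNoise = FALSE, baselineOffset = 0,
                           photonsPerFluor = 500),
    kinetics = kineticsConfig(kOnPseudo = 0, stableFraction = 1,
                              bleachRate = 0, dyesPerDisc = 2),
    discDensity = 1, binderOccupancy = 0, nonspecificDensity = 0,
    nFrames = 5, discFrames = 5, minSeparation = 0, rngSeed = 21)
  f <- simulateField(cfg)
  total <- sum(frames(f$disc)[, , 1])
  expect_equal(total, 1000, tolerance = 1e-4)
})

test_that("ground truth keeps one binder at a time and consistent totals", {
  cfg <- simConfig(
    imaging = imagingModel(fieldEdge = 96),
    kinetics = kineticsConfig(kOff = 0.8, kOnPseudo = 0.5, bleachRate = 0),
    discDensity = 40, binderOccupancy = 1, nonspecificDensity = 0,
    nFrames = 200, rngSeed = 17)
  truth <- simulateField(cfg, channels = character(0))$truth
  expect_true(validObject(truth))  # validity enforces non-overlap
  bi <- truth@bindingIntervals
  expect_true(all(bi$end <= truth@movieLength + 1e-9))
  expect_true(all(bi$visibleEnd <= bi$end + 1e-9))
  ## conservation: per-spot total bound time equals the sum of intervals
  tot <- tapply(bi$end - bi$start, bi$spot, sum)
  expect_true(all(tot <= truth@movieLength + 1e-9))
})
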