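test_that("trace extraction subtracts local background exactly", {
  ## uniform image: aperture sum equals annulus estimate, trace is zero
  uni <- movieStack(array(250, c(32, 32, 6)))
  tr <- extractTrace(uni, 16, 16)
  expect_equal(intensity(tr), rep(0, 6))

  ## noiseless injected spot of known photon count on a flat offset; a
  ## 4-pixel aperture captures all but the far PSF tail
  H <- 32
  arr <- array(120, c(H, H, 4))
  for (t in 1:4)
    arr[, , t] <- arr[, , t] + 600 * NanoSiMPull:::psfPatch(
      16.3, 15.6, 1.0, seq_len(H), seq_len(H))
  tr <- extractTrace(movieStack(arr), 16.3, 15.6, apertureRadius = 4,
                     annulus = c(6, 8))
  expect_equal(intensity(tr), rep(600, 4), tolerance = 0.005)

  expect_error(extractTrace(uni, 3, 16), "too close")
})

test_that("binarization recovers a noiseless square wave exactly", {
  tr <- squareTrace(60, list(c(11, 20), c(35, 36)), level = 100)
  iv <- intervals(binarizeTrace(tr))
  on <- iv[iv$state == "on", ]
  expect_equal(on$start, c(1.0, 3.4))
  expect_equal(on$end, c(2.0, 3.6))
  expect_false(any(on$censored))
  ## first/last intervals are flagged censored
  expect_true(iv$censored[1] && iv$censored[nrow(iv)])

  ## all-zero trace: a single off interval spanning the movie
  iv0 <- intervals(binarizeTrace(trace(rep(0, 50), 0.1)))
  expect_equal(nrow(iv0), 1)
  expect_equal(iv0$state, "off")
  expect_equal(iv0$end - iv0$start, 5)

  ## single-level bright trace classified by the on-level prior
  iv1 <- intervals(binarizeTrace(trace(rep(480, 50), 0.1),
                                 onLevelPrior = 500))
  expect_equal(iv1$state, "on")
})

test_that("binarization is invariant to affine intensity rescaling", {
  set.seed(5)
  y <- rep(c(0, 100, 0, 100, 0), times = c(10, 8, 14, 6, 12)) + rnorm(50, 0, 8)
  a <- intervals(binarizeTrace(trace(y, 0.1)))
  b <- intervals(binarizeTrace(trace(3.7 * y + 250, 0.1)))
  expect_identical(a, b)
})

test_that("on and off intervals tile the movie exactly", {
  set.seed(6)
  for (i in 1:5) {
    y <- rnorm(80, rep(sample(c(0, 120), 8, TRUE), each = 10), 10)
    iv <- intervals(binarizeTrace(trace(y, 0.1)))
    expect_equal(sum(iv$end - iv$start), 8)
    expect_equal(iv$start[-1], head(iv$end, -1))
  }
})

test_that("simulated blinking events are recovered within one frame", {
  nok <- 0; ntot <- 0
  for (i in 1:120) {
    if (ntot >= 50) break
    cfg <- simConfig(
      imaging = imagingModel(fieldEdge = 32),
      kinetics = kineticsConfig(kOff = 0.5, kOnPseudo = 0.1,
                                bleachRate = 0),
      discDensity = 1, binderOccupancy = 1, nonspecificDensity = 0,
      nFrames = 300, minSeparation = 0, rngSeed = 100 + i)
    f <- simulateField(cfg, channels = "protein")
    p <- f$truth@discPositions
    if (p$x[1] < 8 || p$x[1] > 24 || p$y[1] < 8 || p$y[1] > 24) next
    iv <- intervals(binarizeTrace(extractTrace(f$protein, p$x[1], p$y[1])))
    rec <- iv[iv$state == "on" & !iv$censored, ]
    bi <- f$truth@bindingIntervals
    bi <- bi[order(bi$start), ]
    ## only frame-resolvable events: complete, and separated from their
    ## neighbours by more than one frame (closer gaps are unresolvable at
    ## the sampling rate by construction)
    gapBefore <- c(Inf, bi$start[-1] - bi$end[-nrow(bi)])
    gapAfter <- c(bi$start[-1] - bi$end[-nrow(bi)], Inf)
    resolvable <- bi$start > 0 & bi$end < f$truth@movieLength &
      gapBefore > 0.15 & gapAfter > 0.15
    true <- bi[resolvable, ]
    for (j in seq_len(nrow(true))) {
      k <- which(abs(rec$start - true$start[j]) < 0.2)[1]
      ntot <- ntot + 1
      if (!is.na(k) &&
          abs((rec$end[k] - rec$start[k]) -
              (true$end[j] - true$start[j])) <= 0.1 + 1e-9)
        nok <- nok + 1
    }
  }
  expect_gt(ntot, 20)
  expect_gte(nok / ntot, 0.95)
})
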