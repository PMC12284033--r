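test_that("noiseless staircases are classified exactly", {
  ## single drop
  tr <- trace(rep(c(100, 0), times = c(30, 30)), 0.1)
  fit <- fitSteps(tr)
  expect_equal(nSteps(fit), 1L)
  expect_equal(fit@stepTimes, 3.0)
  expect_equal(fit@levels, c(100, 0))

  ## two equal drops
  tr2 <- trace(rep(c(200, 100, 0), times = c(20, 20, 20)), 0.1)
  fit2 <- fitSteps(tr2)
  expect_equal(nSteps(fit2), 2L)
  expect_equal(fit2@levels, c(200, 100, 0))

  expect_error(fitSteps(trace(c(1, 2, 3), 0.1)), "too short")
})

test_that("upward steps and incomplete bleaching are unclassifiable", {
  up <- trace(rep(c(100, 0, 100), times = c(20, 20, 20)), 0.1)
  expect_equal(nSteps(fitSteps(up)), 0L)
  expect_match(fitSteps(up)@reason, "non-monotone")

  ## never reaches background
  high <- trace(rep(c(300, 150), times = c(30, 30)), 0.1)
  expect_match(fitSteps(high)@reason, "above background")

  ## flat trace: no step
  expect_equal(nSteps(fitSteps(trace(rep(100, 60), 0.1))), 0L)
})

test_that("model nesting: restricting below the true step count never
          improves the score", {
  set.seed(9)
  for (i in 1:6) {
    tr <- simulateBleachTrace(3, 0.2, levelPerFluor = 100, nFrames = 300,
                              noiseSd = 15, rngSeed = 40 + i)
    if (tr@metadata$visibleSteps != 3) next
    full <- fitSteps(tr, maxSteps = 4)
    restricted <- fitSteps(tr, maxSteps = 2)
    expect_gte(restricted@score, full@score)
  }
})

test_that("classification accuracy does not improve with more noise", {
  acc <- vapply(c(10, 30, 60), function(noise) {
    hits <- vapply(1:40, function(i) {
      tr <- simulateBleachTrace(1 + (i %% 3), 0.2, levelPerFluor = 100,
                                nFrames = 250, noiseSd = noise,
                                rngSeed = 2000 + i)
      nSteps(fitSteps(tr)) == tr@metadata$visibleSteps
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.05))  # non-increasing up to sampling noise
  expect_gte(acc[1], 0.95)
})

test_that("step distributions summarize classified traces", {
  mkFit <- function(k) {
    if (k == 0)
      new("StepFit", nSteps = 0L, stepTimes = numeric(), levels = 1,
          score = 0, sigma = 1, reason = "test")
    else
      new("StepFit", nSteps = as.integer(k), stepTimes = seq_len(k),
          levels = seq(k, 0), score = 0, sigma = 1, reason = "")
  }
  allOne <- stepDistribution(lapply(1:10, function(i) mkFit(1)))
  expect_equal(allOne@table$percent, c(100, 0, 0, 0))

  quarters <- stepDistribution(lapply(rep(1:4, each = 5), mkFit))
  expect_equal(quarters@table$percent, rep(25, 4))

  mixed <- stepDistribution(c(lapply(c(1, 1, 2), mkFit), list(mkFit(0))))
  expect_equal(mixed@nUnclassified, 1L)
  expect_equal(sum(mixed@table$percent), 100)

  expect_error(stepDistribution(list(mkFit(0))), "no classifiable")

  ## per-assay grouping returns SEM across assays
  grouped <- stepDistribution(lapply(rep(1:2, 10), mkFit),
                              assay = rep(c("a", "b"), each = 10))
  expect_true("sem" %in% names(grouped@table))
  expect_equal(sum(grouped@table$percent), 100)
})

test_that("monomer populations with incomplete bleaching show the analytic
          1-step share", {
  rate <- 0.08; nFr <- 150  # 15 s movie: completion prob 1 - exp(-1.2)
  seen <- vapply(1:300, function(i) {
    tr <- simulateBleachTrace(1, rate, nFrames = nFr, rngSeed = 3000 + i)
    tr@metadata$visibleSteps
  }, integer(1))
  expect_equal(mean(seen == 1), 1 - exp(-rate * nFr * 0.1),
               tolerance = 0.06)
})
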