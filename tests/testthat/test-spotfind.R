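test_that("blank images yield no spots and thresholds act monotonically", {
  blank <- movieStack(array(100, c(64, 64, 3)))
  expect_equal(nSpots(detectSpots(blank)), 0)

  f <- simulateField(smallFieldConfig(seed = 30, nDiscs = 30, edge = 96))
  counts <- vapply(c(3, 5, 8, 12), function(s)
    nSpots(detectSpots(f$disc, snrMin = s)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("injected spots are found within a pixel of their positions", {
  ## deterministic synthetic image: 25 well-separated unit-PSF spots
  set.seed(4)
  H <- 120
  img <- array(0, c(H, H, 1))
  xs <- rep(seq(15, 105, by = 22), times = 5) + runif(25, -3, 3)
  ys <- rep(seq(15, 105, by = 22), each = 5) + runif(25, -3, 3)
  for (i in 1:25)
    img[, , 1] <- img[, , 1] + 800 * NanoSiMPull:::psfPatch(
      xs[i], ys[i], 1.0, seq_len(H), seq_len(H))
  img <- img + array(rnorm(H * H, 100, 8), c(H, H, 1))
  ss <- detectSpots(movieStack(img))
  sc <- detectionScore(ss, data.frame(x = xs, y = ys), radius = 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_lt(sc$rmse, 0.3)
})

test_that("detection is equivariant under integer translation", {
  set.seed(8)
  H <- 80
  base <- array(0, c(H, H, 1))
  xs <- c(20.3, 45.7, 60.2); ys <- c(25.1, 52.8, 38.4)
  for (i in seq_along(xs))
    base[, , 1] <- base[, , 1] + 900 * NanoSiMPull:::psfPatch(
      xs[i], ys[i], 1.0, seq_len(H), seq_len(H))
  noise <- array(rnorm(H * H, 100, 8), c(H, H, 1))
  shift <- 7L
  shifted <- array(0, c(H, H, 1))
  for (i in seq_along(xs))
    shifted[, , 1] <- shifted[, , 1] + 900 * NanoSiMPull:::psfPatch(
      xs[i] + shift, ys[i] + shift, 1.0, seq_len(H), seq_len(H))
  ## same noise field, shifted likewise, so the comparison is exact
  noiseShift <- noise
  noiseShift[(shift + 1):H, (shift + 1):H, 1] <-
    noise[1:(H - shift), 1:(H - shift), 1]
  s1 <- spots(detectSpots(movieStack(base + noise)))
  s2 <- spots(detectSpots(movieStack(shifted + noiseShift)))
  s1 <- s1[order(s1$x), ]; s2 <- s2[order(s2$x), ]
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(s2$x - s1$x, rep(shift, nrow(s1)), tolerance = 0.05)
  expect_equal(s2$y - s1$y, rep(shift, nrow(s1)), tolerance = 0.05)
})

test_that("field counting subtracts background and keeps sign", {
  mk <- function(n) {
    d <- data.frame(x = runif(n, 5, 60), y = runif(n, 5, 60),
                    amplitude = rep(100, n), sigma = 1)
    NanoSiMPull:::spotSet(d, "protein", c(64, 64), 160)
  }
  set.seed(2)
  expect_equal(adjustedCount(countField(mk(40), mk(120))), 80)
  expect_equal(adjustedCount(countField(mk(50), mk(50))), 0)
  expect_equal(adjustedCount(countField(mk(70), mk(30))), -40)
  other <- NanoSiMPull:::spotSet(
    data.frame(x = runif(5, 5, 28), y = runif(5, 5, 28),
               amplitude = 100, sigma = 1), "protein", c(32, 32), 160)
  expect_error(countField(mk(5), other), "different areas")

  ## linearity of the adjusted count
  a <- countField(mk(10), mk(100))
  b <- countField(mk(30), mk(60))
  expect_equal(adjustedCount(a) + adjustedCount(b), 90 + 30)
})

test_that("field summaries give the closed-form mean, SD and SEM", {
  s <- summarizeFields(c(70, 80, 90), minFields = 3)
  expect_equal(s$mean, 80)
  expect_equal(s$sd, 10)
  expect_equal(s$sem, 10 / sqrt(3))
  expect_equal(summarizeFields(rep(80, 12))$sd, 0)
  expect_error(summarizeFields(c(1, 2, 3)), "only 3 fields")
  expect_warning(summarizeFields(c(1, 2, 3), allowFewer = TRUE),
                 "only 3 fields")
})

test_that("mean adjusted count over nonbinder fields tracks the generative
          nonspecific density", {
  counts <- vapply(1:12, function(i) {
    f <- simulateField(simConfig(
      imaging = imagingModel(fieldEdge = 128),
      kinetics = kineticsConfig(bleachRate = 0),
      discDensity = 0, binderOccupancy = 0, nonspecificDensity = 25,
      nFrames = 10, discFrames = 10, rngSeed = 700 + i))
    nSpots(detectSpots(f$protein))
  }, numeric(1))
  ## detector loses only edge-band spots; expected visible fraction
  edgeFrac <- (128 - 6)^2 / 128^2
  expect_equal(mean(counts), 25 * edgeFrac, tolerance = 0.15)
})

test_that("colocalization matches each spot at most once", {
  mk <- function(x, y) NanoSiMPull:::spotSet(
    data.frame(x = x, y = y, amplitude = 100, sigma = 1),
    "disc", c(64, 64), 160)
  a <- mk(c(10, 20, 30), c(10, 20, 30))
  cl <- colocalize(a, mk(c(10, 20, 30), c(10, 20, 30)), radius = 1)
  expect_equal(nrow(cl$pairs), 3)
  expect_length(cl$orphanDiscs, 0)

  empty <- NanoSiMPull:::spotSet(
    data.frame(x = numeric(), y = numeric(), amplitude = numeric(),
               sigma = numeric()), "protein", c(64, 64), 160)
  expect_equal(nrow(colocalize(a, empty)$pairs), 0)

  far <- mk(c(15, 25, 35), c(10, 20, 30))  # offset 5 px > radius 2
  expect_equal(nrow(colocalize(a, far, radius = 2)$pairs), 0)

  ## two proteins near one disc: only one pairs
  b <- mk(c(10.4, 10.8), c(10, 10))
  expect_equal(nrow(colocalize(mk(10, 10), b, radius = 2)$pairs), 1)
})

test_that("movies round-trip through multi-page TIFF", {
  f <- simulateField(smallFieldConfig(seed = 12, nDiscs = 10, edge = 48,
                                      nFrames = 4))
  path <- tempfile(fileext = ".tif")
  writeMovie(f$disc, path)
  back <- readMovie(path, channel = "disc")
  expect_equal(dim(frames(back)), dim(frames(f$disc)))
  expect_equal(frames(back), round(frames(f$disc)), tolerance = 1e-6)
})
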