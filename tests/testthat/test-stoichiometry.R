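test_that("anionic lipid count reproduces the 15% DMPS disc and scales", {
  expect_identical(anionicPerLeaflet(discSpec(anionicFraction = 0.15)), 12)
  expect_identical(anionicPerLeaflet(discSpec(anionicFraction = 0)), 0)
  expect_identical(anionicPerLeaflet(discSpec(anionicFraction = 0.05)), 4)

  ## monotone in fraction and leaflet size
  fr <- seq(0, 0.5, by = 0.05)
  counts <- vapply(fr, function(f)
    anionicPerLeaflet(discSpec(anionicFraction = f)), numeric(1))
  expect_true(all(diff(counts) >= 0))
  sizes <- c(40, 60, 80, 100, 130)
  counts <- vapply(sizes, function(n)
    anionicPerLeaflet(discSpec(lipidsPerLeaflet = n,
                               anionicFraction = 0.15)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("outer-leaflet PIP count gives ~600 for a 50-nm vesicle at 5%", {
  expect_identical(suvAccessiblePipCount(vesicleSpec(50, 0.65, 0.05)), 604)
  expect_identical(suvAccessiblePipCount(vesicleSpec(50, 0.65, 0)), 0)
  ## area scales exactly as diameter squared (un-rounded)
  n50 <- suvAccessiblePipCount(vesicleSpec(50, 0.65, 0.05), round = FALSE)
  n100 <- suvAccessiblePipCount(vesicleSpec(100, 0.65, 0.05), round = FALSE)
  expect_equal(n100 / n50, 4)
  n37 <- suvAccessiblePipCount(vesicleSpec(37, 0.65, 0.05), round = FALSE)
  expect_equal(n37 / n50, (37 / 50)^2)
})

test_that("disc leaflet lipid area is 40 nm^2 for the standard disc", {
  expect_equal(discLipidArea(discSpec()), 40)
  expect_equal(discLipidArea(discSpec(lipidsPerLeaflet = 160)), 80)
  expect_error(discSpec(areaPerLipid = 0), "areaPerLipid")
})

test_that("dye mass fraction is ~1% for the DiD-labelled disc and is scale
          invariant", {
  f <- dyeMassFraction(massModel())
  expect_equal(f, 100 * 2104 / (2104 + 49324 + 108480))
  expect_equal(round(f), 1)
  expect_equal(dyeMassFraction(massModel(nDye = 0)), 0)
  ## doubling every molecular weight leaves the fraction unchanged
  f2 <- dyeMassFraction(massModel(dyeMw = 2 * 1052, scaffoldMw = 2 * 24662,
                                  lipidMw = 2 * 678))
  expect_equal(f2, f)
  expect_true(f >= 0 && f <= 100)
})

test_that("composition validation rejects impossible specs", {
  expect_error(discSpec(anionicFraction = 1.2), "anionicFraction")
  expect_error(discSpec(anionicFraction = 0.7, pipFraction = 0.5), "<= 1")
  expect_error(vesicleSpec(diameter = -10), "diameter")
  expect_error(massModel(dyeMw = 0), "positive")
})

test_that("PIP count is reported per leaflet and per disc", {
  p5 <- discPipCount(discSpec(pipFraction = 0.05))
  p10 <- discPipCount(discSpec(pipFraction = 0.10))
  expect_identical(p5$perLeaflet, 4)
  expect_identical(p5$perDisc, 8)
  expect_identical(p10$perLeaflet, 8)
  expect_identical(p10$perDisc, 16)
})

test_that("composition tables round-trip through CSV and YAML config", {
  specs <- list(control = discSpec(anionicFraction = 0.15),
                pip3 = discSpec(anionicFraction = 0.15, pipFraction = 0.10))
  csv <- tempfile(fileext = ".csv")
  tab <- compositionTable(specs, file = csv)
  expect_equal(nrow(tab), 2L)
  expect_equal(read.csv(csv)$anionicPerLeaflet, c(12, 12))

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("control:", "  anionic_fraction: 0.15",
               "pip3:", "  anionic_fraction: 0.15",
               "  pip_fraction: 0.10"), yml)
  fromYaml <- readDiscConfig(yml)
  expect_equal(compositionTable(fromYaml)$pipPerLeaflet, c(0, 8))
})
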