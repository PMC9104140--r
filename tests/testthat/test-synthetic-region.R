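test_that("region generation is deterministic and seed-sensitive", {
  cfg <- smallConfig()
  r1 <- generateRegion(cfg, seed = 1)
  r2 <- generateRegion(cfg, seed = 1)
  expect_identical(r1, r2)
  r3 <- generateRegion(cfg, seed = 2)
  expect_false(identical(landuse(r1), landuse(r3)))
})

test_that("all region rasters share shape and classes partition the grid", {
  r <- smallRegion()
  dm <- regionDim(r)
  expect_identical(dim(r@altitude), dm)
  expect_identical(dim(r@popCount), dm)
  for (s in c("spring", "summer", "fall", "winter")) {
    expect_identical(dim(climateRaster(r, "temperature", s)), dm)
    expect_identical(dim(climateRaster(r, "precipitation", s)), dm)
  }
  lv <- attr(landuse(r), "levels")
  expect_true(all(landuse(r) %in% seq_along(lv)))
})

test_that("degenerate class mixtures behave as configured", {
  p <- c(governmental = 0.02, commercial = 0.02, residential = 0,
         industrial = 0.02, open_space = 0.1, other = 0.84)
  r <- generateRegion(regionConfig(width = 60, height = 60, nClusters = 3,
                                   classProportions = p), seed = 5)
  lv <- attr(landuse(r), "levels")
  expect_equal(sum(landuse(r) == match("residential", lv)), 0)
  expect_error(regionConfig(classProportions = c(residential = 0.5,
                                                 commercial = 0.6)),
               "configuration error")
})

test_that("site placement honours count, urban weighting and bounds", {
  r <- smallRegion()
  s <- placeSites(r, n = 125, urbanWeight = 0.9, seed = 3)
  expect_equal(nrow(s), 125)
  expect_false(anyDuplicated(s$id) > 0)
  W <- ncol(landuse(r)) * cellSize(r); H <- nrow(landuse(r)) * cellSize(r)
  expect_true(all(s$x > 0 & s$x < W & s$y > 0 & s$y < H))

  lv <- attr(landuse(r), "levels")
  urbanIdx <- match(c("residential", "commercial"), lv)
  allUrban <- placeSites(r, n = 20, urbanWeight = 1, seed = 4)
  onCls <- landuse(r)[cbind(allUrban$row, allUrban$col)]
  expect_true(all(onCls %in% urbanIdx))

  expect_error(placeSites(r, n = 0, seed = 1), "placement error")
  expect_error(placeSites(r, n = 1e7, seed = 1), "placement error")
})

test_that("urban site fraction is monotone in the urban weight", {
  r <- smallRegion()
  lv <- attr(landuse(r), "levels")
  urbanIdx <- match(c("residential", "commercial"), lv)
  fracUrban <- function(w, seed) {
    s <- placeSites(r, n = 20, urbanWeight = w, seed = seed)
    mean(landuse(r)[cbind(s$row, s$col)] %in% urbanIdx)
  }
  weights <- c(0, 0.3, 0.6, 0.9, 1)
  avg <- sapply(weights, function(w)
    mean(sapply(1:10, function(k) fracUrban(w, 100 + k))))
  expect_true(all(diff(avg) >= -0.02))  # non-decreasing up to sampling noise
  expect_equal(avg[length(avg)], 1)
})

test_that("an intercept-only truth model yields the intercept in ppb", {
  r <- smallRegion()
  s <- smallSites(10)
  tm <- methods::new("TruthModel", season = "spring", intercept = 0.023,
                     terms = data.frame(variable = character(0),
                                        radius = numeric(0),
                                        coefficient = numeric(0)),
                     noiseSd = 0)
  conc <- simulateConcentrations(r, s, tm, seed = 1)
  expect_equal(conc$no2_ppb, rep(23, 10))
})

test_that("noiseless simulation equals an independently assembled predictor", {
  r <- smallRegion()
  s <- smallSites(12)
  truth <- defaultTruthModels(noiseSd = 0)
  conc <- simulateConcentrations(r, s, truth, seed = 2)
  specs <- defaultVariableSpecs()
  for (season in c("summer", "winter")) {
    tm <- truth[[season]]
    mu <- rep(tm@intercept, nrow(s))
    for (i in seq_len(nrow(tm@terms))) {
      v <- tm@terms$variable[i]
      seasonal <- specs$seasonal[match(v, specs$name)]
      x <- vapply(seq_len(nrow(s)), function(j)
        seasonalLUR:::extractOne(r, v, s$x[j], s$y[j], tm@terms$radius[i],
                                 season = if (seasonal) season else NULL),
        numeric(1))
      mu <- mu + tm@terms$coefficient[i] * x
    }
    got <- conc$no2_ppb[conc$season == season]
    expect_lt(max(abs(got - 1000 * mu)), 1e-9)
  }
})

test_that("simulated noise matches the requested standard deviation", {
  r <- generateRegion(regionConfig(width = 120, height = 120, nClusters = 6),
                      seed = 21)
  s <- placeSites(r, n = 500, urbanWeight = 0.9, seed = 22)
  tm <- defaultTruthModels(noiseSd = 5)$summer
  mu0 <- suppressWarnings(
    simulateConcentrations(r, s, defaultTruthModels(noiseSd = 0)$summer,
                           seed = 1))$no2_ppb
  conc <- suppressWarnings(simulateConcentrations(r, s, tm, seed = 23))
  resid <- conc$no2_ppb - mu0
  expect_lt(abs(sd(resid) - 5) / 5, 0.1)
})

test_that("unknown truth variables and negative draws are handled", {
  r <- smallRegion(); s <- smallSites(10)
  bad <- methods::new("TruthModel", season = "fall", intercept = 0.02,
                      terms = data.frame(variable = "traffic_volume",
                                         radius = 200, coefficient = 1e-5),
                      noiseSd = 1)
  expect_error(simulateConcentrations(r, s, bad, seed = 1),
               "model specification error")

  low <- methods::new("TruthModel", season = "fall", intercept = 0.0005,
                      terms = data.frame(variable = character(0),
                                         radius = numeric(0),
                                         coefficient = numeric(0)),
                      noiseSd = 5)
  expect_warning(conc <- simulateConcentrations(r, s, low, seed = 3),
                 "clipped")
  expect_true(all(conc$no2_ppb >= 0))
  expect_gt(attr(conc, "clipped")[["fall"]], 0)
})

test_that("climate perturbation changes climate only, exactly", {
  r <- smallRegion()
  same <- rcpPerturbation(r, list())
  expect_identical(same@climate, r@climate)

  fut <- rcpPerturbation(r, list(winter = list(tempOffset = 2),
                                 summer = list(precScale = 0)))
  expect_equal(climateRaster(fut, "temperature", "winter"),
               climateRaster(r, "temperature", "winter") + 2)
  expect_true(all(climateRaster(fut, "precipitation", "summer") == 0))
  expect_identical(landuse(fut), landuse(r))
  expect_identical(roads(fut), roads(r))
  expect_identical(fut@altitude, r@altitude)
  expect_identical(climateRaster(fut, "temperature", "spring"),
                   climateRaster(r, "temperature", "spring"))

  expect_error(rcpPerturbation(r, list(monsoon = list(tempOffset = 1))),
               "unknown season")
})
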