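test_that("pearsonR honours its contracts", {
  expect_equal(pearsonR(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearsonR(c(1, 2, 3), c(3, 2, 1)), -1)
  # cov = 4/3, sds sqrt(5/3) each -> r = 0.8
  expect_equal(pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonR(1:4, 1:5), "equal length")
  expect_error(pearsonR(1:2, 2:3), "at least 3")
})

test_that("selectBuffer maximizes |r| with smallest-radius ties", {
  set.seed(101)
  n <- 60
  y <- rnorm(n)
  radii <- c(100, 200, 300)
  # construct columns with |r| profile (low, high, medium)
  mk <- function(target) target * y + sqrt(1 - target^2) * rnorm(n)
  vals <- cbind(mk(0.1), y + 0.05 * rnorm(n), mk(0.4))
  cube <- manualCube(list(residential_area = vals), radii)
  conc <- manualConc(list(spring = y), cubeSites(cube))
  sel <- selectBuffer(cube, conc, "residential_area")
  expect_equal(sel$buffers$radius, 200)

  # exact tie: identical columns at 100 and 300 -> smallest wins
  cube2 <- manualCube(list(residential_area = cbind(y, 0.2 * rnorm(n), y)),
                      radii)
  sel2 <- selectBuffer(cube2, conc, "residential_area")
  expect_equal(sel2$buffers$radius, 100)
})

test_that("selectBuffer is invariant to site ordering", {
  cube <- smallCube(); conc <- smallConc()
  sel1 <- selectBuffer(cube, conc, "road_length")
  perm <- sample(nrow(cubeTable(cube)))
  cubeP <- methods::new("FeatureCube", table = cubeTable(cube)[perm, ],
                        sites = cubeSites(cube), specs = cube@specs)
  concP <- conc[sample(nrow(conc)), ]
  sel2 <- selectBuffer(cubeP, concP, "road_length")
  expect_equal(sel1$buffers, sel2$buffers)
})

test_that("seasonal variables are selected per season", {
  cube <- smallCube(); conc <- smallConc()
  sel <- selectBuffer(cube, conc, "temperature")
  expect_setequal(sel$buffers$season, c("spring", "summer", "fall", "winter"))
  expect_true(all(sel$buffers$radius %in% seq(100, 1000, 100)))
})

test_that("the first screen drops weak variables and keeps strong ones", {
  set.seed(77)
  n <- 1000
  y <- rnorm(n)
  vals <- list(residential_area = cbind(y + 0.3 * rnorm(n), y + rnorm(n)),
               open_space_area = cbind(rnorm(n), rnorm(n)))
  cube <- manualCube(vals, c(100, 200))
  conc <- manualConc(list(spring = y), cubeSites(cube))
  buffers <- do.call(rbind, lapply(names(vals), function(v)
    cbind(variable = v, selectBuffer(cube, conc, v)$buffers,
          stringsAsFactors = FALSE)))
  fs <- firstScreen(cube, conc, buffers, thresholdLow = 0.2)
  expect_true("residential_area" %in% fs$kept)
  expect_true("open_space_area" %in% fs$dropped)
  # vacuous threshold keeps everything
  fs0 <- firstScreen(cube, conc, buffers, thresholdLow = 0)
  expect_length(fs0$dropped, 0)
})

test_that("the second screen drops the weaker member of collinear pairs", {
  set.seed(55)
  n <- 300
  y <- rnorm(n)
  a <- y + 0.5 * rnorm(n)           # strong
  dup <- a + 0.5 * rnorm(n)         # noisy copy: collinear but weaker
  ortho <- rnorm(n)                 # independent, weakly kept
  vals <- list(residential_area = cbind(a, a),
               population_density = cbind(dup, dup),
               road_length = cbind(ortho + 0.35 * y, ortho))
  cube <- manualCube(vals, c(100, 200))
  conc <- manualConc(list(spring = y), cubeSites(cube))
  buffers <- do.call(rbind, lapply(names(vals), function(v)
    cbind(variable = v, selectBuffer(cube, conc, v)$buffers,
          stringsAsFactors = FALSE)))
  fs <- firstScreen(cube, conc, buffers, 0.1)
  ss <- secondScreen(cube, conc, buffers, fs$kept, fs$rResponse, 0.7)
  expect_true("residential_area" %in% ss$decisive)
  expect_true("road_length" %in% ss$decisive)
  expect_equal(ss$dropped$variable, "population_density")
  expect_equal(ss$dropped$with, "residential_area")
})

test_that("three mutually collinear variables leave exactly one survivor", {
  set.seed(66)
  n <- 400
  y <- rnorm(n)
  base <- y + 0.6 * rnorm(n)
  v1 <- base + 0.10 * rnorm(n)
  v2 <- base + 0.20 * rnorm(n)
  v3 <- base + 0.30 * rnorm(n)
  vals <- list(residential_area = cbind(v1, v1),
               population_density = cbind(v2, v2),
               housing_density = cbind(v3, v3))
  cube <- manualCube(vals, c(100, 200))
  conc <- manualConc(list(spring = y), cubeSites(cube))
  buffers <- do.call(rbind, lapply(names(vals), function(v)
    cbind(variable = v, selectBuffer(cube, conc, v)$buffers,
          stringsAsFactors = FALSE)))
  fs <- firstScreen(cube, conc, buffers, 0.1)
  ss <- secondScreen(cube, conc, buffers, fs$kept, fs$rResponse, 0.7)

  # independent oracle: replay the stated rule by hand
  rResp <- fs$rResponse
  pairs <- t(combn(names(vals), 2))
  pr <- apply(pairs, 1, function(p)
    abs(cor(vals[[p[1]]][, 1], vals[[p[2]]][, 1])))
  ord <- order(pr, decreasing = TRUE)
  droppedOracle <- character(0)
  for (k in ord) {
    if (pr[k] <= 0.7) next
    a <- pairs[k, 1]; b <- pairs[k, 2]
    if (a %in% droppedOracle || b %in% droppedOracle) next
    droppedOracle <- c(droppedOracle,
                       if (rResp[a] < rResp[b]) a else b)
  }
  expect_setequal(ss$dropped$variable, droppedOracle)
  expect_length(ss$decisive, 1)
  expect_equal(ss$decisive, names(which.max(rResp)))
})

test_that("screenVariables is deterministic and reports every variable", {
  cube <- smallCube(); conc <- smallConc()
  rep1 <- screenVariables(cube, conc)
  rep2 <- screenVariables(cube, conc)
  expect_identical(rep1@status, rep2@status)
  expect_identical(rep1@buffers, rep2@buffers)
  expect_setequal(rep1@status$variable, defaultVariableSpecs()$name)
  expect_false(anyDuplicated(rep1@status$variable) > 0)
  expect_true(all(rep1@status$status %in%
                    c("kept", "dropped_low_response_corr",
                      "dropped_collinear", "dropped_stepwise")))
})

test_that("screening recovers the generating structure across seeds", {
  # truth variables kept, population density eliminated as collinear with
  # residential area, at 500 sites and 2 ppb noise
  truth2 <- defaultTruthModels(noiseSd = 2)
  nSeed <- 12
  hits <- logical(nSeed)
  for (k in seq_len(nSeed)) {
    region <- generateRegion(regionConfig(), seed = 400 + 13 * k)
    sites <- placeSites(region, 500, urbanWeight = 0.9, seed = 500 + 13 * k)
    conc <- suppressWarnings(
      simulateConcentrations(region, sites, truth2, seed = 600 + 13 * k))
    cube <- buildFeatureCube(region, sites, defaultVariableSpecs())
    st <- screenVariables(cube, conc)@status
    status <- stats::setNames(st$status, st$variable)
    hits[k] <- all(status[c("road_length", "commercial_area",
                            "residential_area", "temperature",
                            "precipitation")] == "kept") &&
      status[["population_density"]] == "dropped_collinear"
  }
  expect_gte(mean(hits), 0.9)
})

test_that("an all-noise response fails the screen loudly", {
  cube <- smallCube()
  set.seed(9)
  conc <- manualConc(list(spring = rnorm(length(cubeSites(cube)))),
                     cubeSites(cube))
  expect_error(screenVariables(cube, conc, thresholdLow = 0.99),
               "screening error")
})
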