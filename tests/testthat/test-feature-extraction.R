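test_that("road length clips segments against the disc exactly", {
  expect_equal(roadLengthInBuffer(0, 0, list(), 200), 0)
  # chord through the center: a diameter of the 200 m disc
  seg <- list(cbind(x = c(-1000, 1000), y = c(0, 0)))
  expect_equal(roadLengthInBuffer(0, 0, seg, 200), 400)
  # off-center chord at height 100 in a 200 m disc: 2*sqrt(200^2-100^2)
  seg2 <- list(cbind(x = c(-1000, 1000), y = c(100, 100)))
  expect_equal(roadLengthInBuffer(0, 0, seg2, 200), 2 * sqrt(200^2 - 100^2))
})

test_that("road length agrees with a dense point-sampling oracle", {
  set.seed(99)
  for (k in 1:5) {
    p1 <- runif(2, -400, 400); p2 <- runif(2, -400, 400)
    radius <- runif(1, 100, 300)
    got <- roadLengthInBuffer(0, 0, list(rbind(p1, p2)), radius)
    nPts <- 1e5
    t <- (seq_len(nPts) - 0.5) / nPts
    px <- p1[1] + t * (p2[1] - p1[1]); py <- p1[2] + t * (p2[2] - p1[2])
    segLen <- sqrt(sum((p2 - p1)^2))
    oracle <- sum(px^2 + py^2 <= radius^2) * segLen / nPts
    expect_lt(abs(got - oracle), max(0.001 * max(got, oracle), 0.02))
  }
})

test_that("land-use area follows the cell-center rule", {
  r <- manualRegion(20, 20, landuseClass = "residential")
  # site at a cell center, radius below half a cell: own cell only
  expect_equal(landuseAreaInBuffer(r, "residential", 45, 45, 10), 900)
  expect_equal(landuseAreaInBuffer(r, "commercial", 45, 45, 300), 0)
  expect_error(landuseAreaInBuffer(r, "parkland", 45, 45, 300),
               "specification error")
})

test_that("area, density and climate extractions match exhaustive scans", {
  set.seed(17)
  nr <- 25; nc <- 25; cs <- 30
  lv <- c("governmental", "commercial", "residential", "industrial",
          "open_space", "other")
  r <- manualRegion(nr, nc)
  r@landuse[] <- sample(seq_along(lv), nr * nc, replace = TRUE)
  r@popCount[] <- rpois(nr * nc, 40)
  r@climate$fall$temperature[] <- rnorm(nr * nc)

  cx <- cellCenterX <- function(col) (col - 0.5) * cs
  scan <- function(x, y, radius) {
    hits <- integer(0)
    for (row in 1:nr) for (col in 1:nc) {
      if (((col - 0.5) * cs - x)^2 + ((row - 0.5) * cs - y)^2 <= radius^2) {
        hits <- c(hits, (col - 1L) * nr + row)
      }
    }
    hits
  }
  for (case in 1:4) {
    x <- runif(1, 100, nc * cs - 100); y <- runif(1, 100, nr * cs - 100)
    radius <- sample(c(100, 200, 350), 1)
    idx <- scan(x, y, radius)
    expect_equal(landuseAreaInBuffer(r, "residential", x, y, radius),
                 sum(r@landuse[idx] == match("residential", lv)) * cs^2)
    nom <- sum(outer((seq(-15, nr + 15) - 0.5) * cs - y,
                     (seq(-15, nc + 15) - 0.5) * cs - x,
                     function(a, b) a^2 + b^2) <= radius^2)
    expect_equal(densityInBuffer(r@popCount, x, y, radius, region = r),
                 sum(r@popCount[idx]) / (nom * cs^2))
    expect_equal(climateMeanInBuffer(r, "temperature", "fall", x, y, radius),
                 mean(r@climate$fall$temperature[idx]))
  }
})

test_that("density and climate means handle uniform and degenerate input", {
  r <- manualRegion(20, 20)
  r@popCount[] <- 36
  # uniform counts: c per cell over cell area, interior site
  expect_equal(densityInBuffer(r@popCount, 300, 300, 150, region = r),
               36 / 900)
  r@popCount[] <- 0
  expect_equal(densityInBuffer(r@popCount, 300, 300, 150, region = r), 0)
  # radius below the resolution: no cell center falls in the disc
  expect_error(densityInBuffer(r@popCount, 30, 30, 5, region = r),
               "radius below")

  expect_equal(climateMeanInBuffer(r, "temperature", "spring", 300, 300, 200),
               10)
  # radius covering the whole region: global mean
  r2 <- manualRegion(10, 10)
  r2@climate$spring$temperature[] <- seq_len(100)
  expect_equal(climateMeanInBuffer(r2, "temperature", "spring", 150, 150,
                                   1e4),
               mean(seq_len(100)))
})

test_that("distance to coast is the nearest-point distance", {
  coast <- cbind(x = c(0, 0, 100), y = c(0, 500, 800))
  expect_equal(distanceToCoast(0, 500, coast), 0)
  expect_equal(distanceToCoast(100, 250, coast), 100)
  # dense vertex-sampling oracle on a random polyline
  set.seed(5)
  poly <- cbind(x = cumsum(runif(6, -200, 200)),
                y = cumsum(runif(6, -200, 200)))
  x <- 321; y <- -123
  t <- seq(0, 1, length.out = 2001)
  dense <- do.call(rbind, lapply(1:5, function(i)
    cbind(poly[i, 1] + t * (poly[i + 1, 1] - poly[i, 1]),
          poly[i, 2] + t * (poly[i + 1, 2] - poly[i, 2]))))
  oracle <- min(sqrt((dense[, 1] - x)^2 + (dense[, 2] - y)^2))
  expect_lt(abs(distanceToCoast(x, y, poly) - oracle), 0.5)
  expect_error(distanceToCoast(1, 1, cbind(x = 5, y = 5)), "coastline")
})

test_that("the cube is complete, consistent with single calls, and counted", {
  r <- smallRegion()
  s <- smallSites(8)
  specs <- defaultVariableSpecs()
  cube <- buildFeatureCube(r, s, specs)
  # entries per site: road 10 + landuse 5x10 + density 2x10 + altitude 10 +
  # distance 1 + climate 3 vars x 4 seasons x 10 radii
  perSite <- 10 + 50 + 20 + 10 + 1 + 120
  expect_equal(nrow(cubeTable(cube)), nrow(s) * perSite)
  expect_false(anyNA(cubeTable(cube)$value))

  i <- 3
  expect_equal(featureValues(cube, "residential_area", 500)[[i]],
               landuseAreaInBuffer(r, "residential", s$x[i], s$y[i], 500))
  expect_equal(featureValues(cube, "road_length", 300)[[i]],
               roadLengthInBuffer(s$x[i], s$y[i], roads(r), 300))
  expect_equal(featureValues(cube, "temperature", 400, "winter")[[i]],
               climateMeanInBuffer(r, "temperature", "winter",
                                   s$x[i], s$y[i], 400))
  expect_equal(featureValues(cube, "population_density", 800)[[i]],
               densityInBuffer(r@popCount, s$x[i], s$y[i], 800, region = r))
  expect_equal(featureValues(cube, "distance_to_coast")[[i]],
               distanceToCoast(s$x[i], s$y[i], coastline(r)))

  one <- buildFeatureCube(r, s[1, ],
                          defaultVariableSpecs(radii = 200)[2, ])
  expect_equal(nrow(cubeTable(one)), 1L)
})

test_that("sums are monotone in the radius", {
  r <- smallRegion(); s <- smallSites(6)
  cube <- smallCube()
  for (v in c("road_length", "residential_area", "commercial_area")) {
    for (id in cubeSites(cube)[1:6]) {
      prof <- sapply(seq(100, 1000, 100), function(rad)
        featureValues(cube, v, rad)[[id]])
      expect_true(all(diff(prof) >= -1e-9))
    }
  }
})

test_that("extractions are invariant under whole-grid translation", {
  r <- manualRegion(24, 24)
  set.seed(31)
  r@landuse[] <- sample(1:6, 24 * 24, replace = TRUE)
  shift <- 5L  # cells
  r2 <- r
  r2@landuse <- r@landuse * 0L + 6L
  r2@landuse[(1 + shift):24, (1 + shift):24] <-
    r@landuse[1:(24 - shift), 1:(24 - shift)]
  attr(r2@landuse, "levels") <- attr(r@landuse, "levels")
  x <- 330; y <- 290; radius <- 220
  expect_equal(
    landuseAreaInBuffer(r, "industrial", x, y, radius),
    landuseAreaInBuffer(r2, "industrial", x + shift * 30, y + shift * 30,
                        radius))
})

test_that("focal rasters reproduce site extraction at cell centers", {
  r <- smallRegion()
  set.seed(13)
  cells <- cbind(row = sample(10:70, 20), col = sample(10:70, 20))
  xs <- (cells[, "col"] - 0.5) * cellSize(r)
  ys <- (cells[, "row"] - 0.5) * cellSize(r)
  terms <- data.frame(
    variable = c("residential_area", "temperature", "population_density"),
    radius = c(400, 400, 700), stringsAsFactors = FALSE)
  ff <- focalFeatures(r, terms, season = "winter")
  for (i in seq_len(20)) {
    expect_equal(ff[["residential_area@400"]][cells[i, 1], cells[i, 2]],
                 landuseAreaInBuffer(r, "residential", xs[i], ys[i], 400))
    expect_equal(ff[["temperature@400@winter"]][cells[i, 1], cells[i, 2]],
                 climateMeanInBuffer(r, "temperature", "winter",
                                     xs[i], ys[i], 400),
                 tolerance = 1e-9)
    expect_equal(ff[["population_density@700"]][cells[i, 1], cells[i, 2]],
                 densityInBuffer(r@popCount, xs[i], ys[i], 700, region = r),
                 tolerance = 1e-12)
  }
})

test_that("focal road length approximates exact clipping", {
  # dense synthetic network (grid of streets every 150 m): buffers hold
  # substantial road and the rasterized focal sum is within 2 percent
  nr <- 60; cs <- 30
  grid <- c(lapply(seq(2, 58, by = 4), function(k)
    cbind(x = c(0, nr * cs), y = rep((k - 0.5) * cs, 2))),
    lapply(seq(2, 58, by = 4), function(k)
      cbind(x = rep((k - 0.5) * cs, 2), y = c(0, nr * cs))))
  r <- manualRegion(nr, nr, roads = grid)
  ff <- focalFeatures(r, data.frame(variable = "road_length", radius = 600))
  rast <- ff[["road_length@600"]]
  set.seed(3)
  cells <- cbind(row = sample(25:35, 10, replace = TRUE),
                 col = sample(25:35, 10, replace = TRUE))
  exact <- vapply(seq_len(10), function(i)
    roadLengthInBuffer((cells[i, 2] - 0.5) * cs, (cells[i, 1] - 0.5) * cs,
                       grid, 600), numeric(1))
  expect_lt(max(abs(rast[cells] - exact) / exact), 0.02)

  # sparse fixture network: the error is bounded by boundary-cell chords
  r2 <- smallRegion()
  ff2 <- focalFeatures(r2, data.frame(variable = "road_length", radius = 300))
  cells2 <- cbind(row = sample(15:65, 30), col = sample(15:65, 30))
  exact2 <- vapply(seq_len(30), function(i)
    roadLengthInBuffer((cells2[i, 2] - 0.5) * 30, (cells2[i, 1] - 0.5) * 30,
                       roads(r2), 300), numeric(1))
  expect_lt(max(abs(ff2[["road_length@300"]][cells2] - exact2)), 150)

  # total network length is conserved by rasterization
  totalRaster <- sum(seasonalLUR:::rasterizeRoads(r2))
  segs <- seasonalLUR:::polylineSegments(roads(r2))
  totalVector <- sum(seasonalLUR:::segmentLengths(segs))
  expect_equal(totalRaster, totalVector, tolerance = 1e-9)
})

test_that("focal edge cases: constants, empty networks, tiny radii", {
  r <- manualRegion(20, 20, temperature = 3.5)
  ff <- focalFeatures(r, data.frame(variable = "temperature", radius = 200),
                      season = "summer")
  expect_true(all(abs(ff[["temperature@200@summer"]] - 3.5) < 1e-9))
  ffr <- focalFeatures(r, data.frame(variable = "road_length", radius = 200))
  expect_true(all(ffr[["road_length@200"]] == 0))
  expect_error(focalFeatures(r, data.frame(variable = "altitude", radius = 10)),
               "at least one cell")
})
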