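# Shared fixtures, built once per test run. The small region keeps unit
# tests fast; acceptance tests build full-size regions themselves.

.fixtures <- new.env(parent = emptyenv())

smallConfig <- function() {
  # a higher residential share than the full-size default keeps the site
  # pool comfortable on an 80 x 80 grid
  regionConfig(width = 80, height = 80, nClusters = 4,
               classProportions = c(governmental = 0.012,
                                    commercial = 0.031,
                                    residential = 0.030,
                                    industrial = 0.012,
                                    open_space = 0.100,
                                    other = 0.815))
}

smallRegion <- function() {
  if (is.null(.fixtures$region)) {
    .fixtures$region <- generateRegion(smallConfig(), seed = 42)
  }
  .fixtures$region
}

smallSites <- function(n = 60) {
  key <- paste0("sites", n)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- placeSites(smallRegion(), n = n, urbanWeight = 0.9,
                                   seed = 7)
  }
  .fixtures[[key]]
}

smallConc <- function() {
  if (is.null(.fixtures$conc)) {
    .fixtures$conc <- suppressWarnings(
      simulateConcentrations(smallRegion(), smallSites(),
                             defaultTruthModels(), seed = 11))
  }
  .fixtures$conc
}

smallCube <- function() {
  if (is.null(.fixtures$cube)) {
    .fixtures$cube <- buildFeatureCube(smallRegion(), smallSites(),
                                       defaultVariableSpecs())
  }
  .fixtures$cube
}

# A minimal hand-built region for geometry oracles: everything explicit.
manualRegion <- function(nr = 30, nc = 30, cellSize = 30,
                         landuseClass = "other", roads = list(),
                         altitude = 0, temperature = 10) {
  lv <- c("governmental", "commercial", "residential", "industrial",
          "open_space", "other")
  lu <- matrix(match(landuseClass, lv), nr, nc)
  attr(lu, "levels") <- lv
  zero <- matrix(0, nr, nc)
  alt <- matrix(altitude, nr, nc)
  climate <- stats::setNames(lapply(1:4, function(i)
    list(temperature = matrix(temperature, nr, nc),
         precipitation = zero, windSpeed = zero)),
    c("spring", "summer", "fall", "winter"))
  coast <- cbind(x = c(0, 0), y = c(0, nr * cellSize))
  methods::new("SyntheticRegion", cellSize = cellSize, landuse = lu,
               roads = roads, coastline = coast, altitude = alt,
               popCount = zero, housingCount = zero, climate = climate,
               siteSuit = zero, seed = 0L, config = list())
}

# Hand-built feature cube from a named list variable -> matrix of values
# (rows = sites, one column per radius) or vector (static / distance).
manualCube <- function(values, radii, seasonal = character(0),
                       siteIds = NULL) {
  n <- if (is.matrix(values[[1]])) nrow(values[[1]]) else length(values[[1]])
  if (is.null(siteIds)) siteIds <- sprintf("s%03d", seq_len(n))
  rows <- list()
  for (v in names(values)) {
    val <- values[[v]]
    if (is.matrix(val)) {
      for (j in seq_along(radii)) {
        if (v %in% seasonal) {
          for (s in c("spring", "summer", "fall", "winter")) {
            rows[[length(rows) + 1L]] <- data.frame(
              site = siteIds, variable = v, radius = radii[j], season = s,
              value = val[, j], stringsAsFactors = FALSE)
          }
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            site = siteIds, variable = v, radius = radii[j],
            season = NA_character_, value = val[, j], stringsAsFactors = FALSE)
        }
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        site = siteIds, variable = v, radius = NA_real_,
        season = NA_character_, value = val, stringsAsFactors = FALSE)
    }
  }
  specs <- defaultVariableSpecs(radii = radii)
  specs <- specs[specs$name %in% names(values), ]
  extra <- setdiff(names(values), specs$name)
  for (v in extra) {
    specs <- rbind(specs, data.frame(name = v, category = "other",
                                     kind = "area_sum",
                                     seasonal = v %in% seasonal,
                                     radii = I(list(radii))))
  }
  methods::new("FeatureCube",
               table = do.call(rbind, rows), sites = siteIds, specs = specs)
}

# Concentration table from a named list season -> numeric vector.
manualConc <- function(bySeason, siteIds) {
  do.call(rbind, lapply(names(bySeason), function(s)
    data.frame(id = siteIds, season = s, no2_ppb = bySeason[[s]],
               stringsAsFactors = FALSE)))
}
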