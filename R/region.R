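#' Region generator configuration
#'
#' Assembles (and validates) the parameter list consumed by
#' [generateRegion()]. Defaults describe the package's default fixture: a
#' 200 x 200 cell (6 x 6 km) planar region on a 30 m grid, a handful of
#' urban clusters holding the commercial/residential cells, a sparse road
#' network connecting them, a western coastline, and smooth per-season
#' climate surfaces. See the methods vignette for how the contrast scales
#' were chosen.
#'
#' @param width,height grid size in cells (>= 50).
#' @param cellSize cell edge in metres.
#' @param classProportions named proportions over the six land-use classes;
#'   must be non-negative and sum to 1.
#' @param nClusters number of urban cluster seeds.
#' @param clusterSd Gaussian radius of a cluster bump, in cells.
#' @param urbanRange correlation length (cells) of the smooth part of the
#'   urbanization score.
#' @param roadsPerCluster short local road segments laid per cluster.
#' @param climate per-variable list with `mean` (named per season), `sd`
#'   (spatial standard deviation of the surface) and `range` (correlation
#'   length in cells); precipitation and wind are floored at zero.
#' @param altitude list: `base` (m), `sd`, `range`, `urbanEffect` (additive
#'   score pulling clusters into lowlands).
#' @param population list: `perResCell` (count per residential cell),
#'   `noiseSd`, `noiseRange` for the smooth off-residential component.
#' @param housing list: `scale`, `range` for the (land-use independent)
#'   housing count field.
#' @return validated configuration list.
#' @export
regionConfig <- function(width = 400, height = 400, cellSize = 30,
                         classProportions = c(governmental = 0.012,
                                              commercial = 0.031,
                                              residential = 0.009,
                                              industrial = 0.012,
                                              open_space = 0.100,
                                              other = 0.836),
                         nClusters = 40, clusterSd = 8, urbanRange = 25,
                         roadsPerCluster = 1,
                         climate = list(
                           temperature = list(
                             mean = c(spring = 12, summer = 25, fall = 14, winter = -2),
                             sd = 85, range = 40),
                           precipitation = list(
                             mean = c(spring = 150, summer = 600, fall = 215, winter = 50),
                             sd = 100, range = 30),
                           windSpeed = list(
                             mean = c(spring = 3.2, summer = 2.6, fall = 2.8, winter = 3.5),
                             sd = 1.2, range = 20)),
                         altitude = list(base = 150, sd = 120, range = 30,
                                         urbanEffect = -100),
                         population = list(perResCell = 120, noiseSd = 100,
                                           noiseRange = 2),
                         housing = list(scale = 40, range = 6)) {
  stopIfNot(width >= 50 && height >= 50,
            "region must be at least 50 x 50 cells")
  stopIfNot(cellSize > 0, "cellSize must be positive")
  p <- classProportions
  if (is.null(names(p)) || !setequal(names(p), LANDUSE_CLASSES) ||
      any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("configuration error: classProportions must be named over the six ",
         "land-use classes, non-negative, and sum to 1", call. = FALSE)
  }
  for (v in c("temperature", "precipitation", "windSpeed")) {
    cl <- climate[[v]]
    stopIfNot(!is.null(cl) && setequal(names(cl$mean), SEASONS),
              sprintf("climate$%s needs per-season means", v))
  }
  list(width = as.integer(width), height = as.integer(height),
       cellSize = cellSize, classProportions = p[LANDUSE_CLASSES],
       nClusters = as.integer(nClusters), clusterSd = clusterSd,
       urbanRange = urbanRange, roadsPerCluster = as.integer(roadsPerCluster),
       climate = climate, altitude = altitude, population = population,
       housing = housing)
}

#' Generate a synthetic metropolitan region
#'
#' Draws the full toy geography from a seed: a categorical land-use raster
#' whose commercial/residential cells concentrate in a few contiguous urban
#' clusters, a road network connecting the clusters plus local streets,
#' a coastline along the western edge, altitude, population and housing
#' count rasters, and smooth per-season climate surfaces. Deterministic:
#' the same `config` and `seed` reproduce the region bit-for-bit.
#'
#' @param config list from [regionConfig()].
#' @param seed integer seed.
#' @return a [SyntheticRegion-class].
#' @examples
#' region <- generateRegion(regionConfig(width = 60, height = 60), seed = 1)
#' region
#' @export
generateRegion <- function(config = regionConfig(), seed = 1) {
  if (is.null(config$classProportions)) config <- do.call(regionConfig, config)
  withSeed(seed, {
    nr <- config$height; nc <- config$width; cs <- config$cellSize

    # urbanization score: cluster bumps + smooth background
    ctrRow <- stats::runif(config$nClusters, 0.1 * nr, 0.9 * nr)
    ctrCol <- stats::runif(config$nClusters, 0.1 * nc, 0.9 * nc)
    bumps <- matrix(0, nr, nc)
    rows <- seq_len(nr); cols <- seq_len(nc)
    for (k in seq_len(config$nClusters)) {
      bumps <- bumps + outer(exp(-(rows - ctrRow[k])^2 / (2 * config$clusterSd^2)),
                             exp(-(cols - ctrCol[k])^2 / (2 * config$clusterSd^2)))
    }
    if (stats::sd(bumps) > 0) bumps <- (bumps - mean(bumps)) / stats::sd(bumps)
    U <- 0.7 * bumps + 0.3 * smoothField(nr, nc, config$urbanRange)

    # commercial districts are compact cores of roughly 100 m radius: the
    # number of cores is set so each holds about one 100 m disc of cells,
    # making the commercial area within any buffer of >= 100 m essentially
    # the same saturated quantity (larger buffers only add surroundings)
    # cores sit on a jittered regular lattice (central-place-style spacing),
    # so the count of cores within any large buffer is nearly constant
    # everywhere and carries no spurious large-radius signal; centers snap
    # to cell centers so each core is exactly the cell set of a 100 m disc
    nCoresTarget <- max(2L, round(config$classProportions[["commercial"]] *
                                    nr * nc / 37))
    sp <- sqrt(nr * nc / nCoresTarget)
    lattice <- expand.grid(r = seq(sp / 2, nr - sp / 4, by = sp),
                           c = seq(sp / 2, nc - sp / 4, by = sp))
    nCores <- nrow(lattice)
    coreRow <- round(pmin(pmax(lattice$r + stats::rnorm(nCores, 0, 1), 5), nr - 4))
    coreCol <- round(pmin(pmax(lattice$c + stats::rnorm(nCores, 0, 1), 5), nc - 4))
    comScore <- matrix(0, nr, nc)
    for (k in seq_len(nCores)) {
      comScore <- pmax(comScore,
                       outer(exp(-(rows - coreRow[k])^2 / (2 * 2^2)),
                             exp(-(cols - coreCol[k])^2 / (2 * 2^2))))
    }

    # per-class preference scores; class coupling to U controls how strongly
    # the class clings to the urban cores
    score <- list(
      commercial   = comScore + 0.01 * smoothField(nr, nc, 2),
      # commercial districts displace housing: no residential within ~420 m
      # of a core center
      residential  = 0.85 * smoothField(nr, nc, 1) -
        1e6 * (comScore > exp(-14^2 / 18)),
      industrial   = 0.25 * U + 0.95 * smoothField(nr, nc, 7),
      governmental = 0.30 * U + 0.95 * smoothField(nr, nc, 5),
      open_space   = 0.15 * U + 0.90 * smoothField(nr, nc, 10)
    )
    lu <- assignClasses(score, config$classProportions, nr, nc)

    # roads: chain through cluster centres (nearest-neighbour order) plus
    # short local streets around each cluster
    roadList <- buildRoads(ctrRow, ctrCol, config, nr, nc)

    # coastline along the western edge (gentle wiggle, inside the region)
    cy <- seq(0, nr * cs, length.out = 41)
    cx <- 2 * cs + 1.2 * cs * sin(cy / (nr * cs) * 4 * pi) +
      cumsum(stats::rnorm(41, 0, 0.15 * cs))
    coast <- cbind(x = pmax(cx, 0.2 * cs), y = cy)

    # altitude: smooth relief, urban clusters preferentially in lowlands
    alt <- pmax(config$altitude$base +
                  config$altitude$sd * smoothField(nr, nc, config$altitude$range) +
                  config$altitude$urbanEffect * U, 0)

    # population lives on residential cells with heterogeneous per-cell
    # density, so population density in a buffer is a noisy monotone
    # function of the residential area; housing is an independent field
    # (no true link to the response)
    resInd <- (lu == match("residential", LANDUSE_CLASSES)) * 1
    popNoise <- smoothField(nr, nc, config$population$noiseRange)
    popCount <- round(pmax(config$population$perResCell +
                             config$population$noiseSd * popNoise, 0) * resInd)
    housingCount <- round(config$housing$scale *
                            pmax(smoothField(nr, nc, config$housing$range), 0))

    # site suitability: urbanized cells carry the mass; commercial cells
    # are weighted sharply toward core centers (district-center monitors),
    # with commercial and residential holding equal total mass
    resMask <- lu == match("residential", LANDUSE_CLASSES)
    comMask <- lu == match("commercial", LANDUSE_CLASSES)
    # monitoring-network emulation: commercial monitors sit on district
    # center cells; residential monitors sit mid-neighbourhood, in the
    # interstitial band between commercial districts (so every site sees a
    # near-identical count of surrounding districts at any large radius)
    bLo <- (0.45 * sp)^2 / 18; bHi <- (0.60 * sp)^2 / 18
    band <- comScore >= exp(-bHi) & comScore <= exp(-bLo)
    siteSuit <- (resMask & band) * 1
    if (!any(siteSuit > 0)) siteSuit <- resMask * 1
    if (any(comMask)) {
      cw <- (comScore[comMask] > exp(-1 / 18)) * 1
      nresw <- sum(siteSuit)
      if (sum(cw) > 0 && nresw > 0) cw <- cw / sum(cw) * nresw
      siteSuit[comMask] <- cw
    }

    climate <- stats::setNames(lapply(SEASONS, function(s) {
      mk <- function(v, floorZero) {
        cl <- config$climate[[v]]
        f <- cl$mean[[s]] + cl$sd * smoothField(nr, nc, cl$range)
        if (floorZero) f <- pmax(f, 0)
        f
      }
      list(temperature = mk("temperature", FALSE),
           precipitation = mk("precipitation", TRUE),
           windSpeed = mk("windSpeed", TRUE))
    }), SEASONS)

    methods::new("SyntheticRegion", cellSize = cs, landuse = lu,
                 roads = roadList, coastline = coast, altitude = alt,
                 popCount = popCount, housingCount = housingCount,
                 climate = climate, siteSuit = siteSuit,
                 seed = as.integer(seed), config = config)
  })
}

# Exact-proportion sequential assignment: for each class in a fixed order,
# claim the top share of still-unassigned cells by that class's score.
assignClasses <- function(score, proportions, nr, nc) {
  ncell <- nr * nc
  lu <- matrix(0L, nr, nc)
  order_ <- c("commercial", "residential", "industrial", "governmental",
              "open_space")
  for (cls in order_) {
    nWant <- round(proportions[[cls]] * ncell)
    if (nWant <= 0) next
    s <- score[[cls]]
    s[lu != 0L] <- -Inf
    pick <- order(s, decreasing = TRUE)[seq_len(min(nWant, sum(lu == 0L)))]
    lu[pick] <- match(cls, LANDUSE_CLASSES)
  }
  lu[lu == 0L] <- match("other", LANDUSE_CLASSES)
  attr(lu, "levels") <- LANDUSE_CLASSES
  lu
}

buildRoads <- function(ctrRow, ctrCol, config, nr, nc) {
  cs <- config$cellSize
  cx <- cellCenterX(ctrCol, cs); cy <- cellCenterY(ctrRow, cs)
  k <- length(cx)
  roadList <- list()
  if (k >= 2) {
    # greedy nearest-neighbour chain through the cluster centres
    left <- seq_len(k); path <- left[1]; left <- left[-1]
    while (length(left)) {
      last <- path[length(path)]
      d <- (cx[left] - cx[last])^2 + (cy[left] - cy[last])^2
      nxt <- left[which.min(d)]
      path <- c(path, nxt); left <- setdiff(left, nxt)
    }
    # bypass-style connectors: each runs from the periphery of one cluster
    # to the periphery of the next, keeping the arterials out of the dense
    # cores where the monitoring sites sit
    skirt <- 3 * config$clusterSd * cs
    for (i in seq_len(length(path) - 1)) {
      a <- path[i]; b <- path[i + 1]
      dx <- cx[b] - cx[a]; dy <- cy[b] - cy[a]
      len <- sqrt(dx^2 + dy^2)
      if (len <= 2 * skirt) next
      ux <- dx / len; uy <- dy / len
      ex <- cx[a] + skirt * ux; ey <- cy[a] + skirt * uy
      fx <- cx[b] - skirt * ux; fy <- cy[b] - skirt * uy
      mx <- (ex + fx) / 2 - uy * stats::rnorm(1, 0, 6 * cs)
      my <- (ey + fy) / 2 + ux * stats::rnorm(1, 0, 6 * cs)
      roadList[[length(roadList) + 1L]] <-
        cbind(x = c(ex, mx, fx), y = c(ey, my, fy))
    }
  }
  # local streets: short segments on a ring around each cluster core
  for (j in seq_len(k)) {
    for (i in seq_len(config$roadsPerCluster)) {
      rho <- stats::runif(1, 1.5, 3.5) * config$clusterSd * cs
      theta <- stats::runif(1, 0, 2 * pi)
      ox <- cx[j] + rho * cos(theta)
      oy <- cy[j] + rho * sin(theta)
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 120, 300)
      roadList[[length(roadList) + 1L]] <-
        cbind(x = c(ox - cos(ang) * len / 2, ox + cos(ang) * len / 2),
              y = c(oy - sin(ang) * len / 2, oy + sin(ang) * len / 2))
    }
  }
  # clamp to region bounds
  W <- nc * cs; H <- nr * cs
  lapply(roadList, function(p) {
    p[, 1] <- pmin(pmax(p[, 1], 0), W)
    p[, 2] <- pmin(pmax(p[, 2], 0), H)
    p
  })
}

#' Place monitoring sites
#'
#' Samples `n` distinct cells (without replacement) as monitoring sites,
#' weighting urbanized cells (residential or commercial land use) by
#' `urbanWeight` against a uniform background of `1 - urbanWeight`, so that
#' `urbanWeight = 1` places every site on an urbanized cell. Sites sit at
#' cell centers; each carries a zone label (`incheon`/`seoul`/`gyeonggi` by
#' west-to-east thirds, echoing the coastal-to-inland layout of a Korean
#' capital-region network).
#'
#' @param region a [SyntheticRegion-class].
#' @param n number of sites (>= 1); the default fixture uses 125.
#' @param urbanWeight fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `x`, `y`, `zone`, plus integer
#'   columns `row`, `col`.
#' @examples
#' region <- generateRegion(regionConfig(width = 60, height = 60), seed = 1)
#' head(placeSites(region, n = 10, seed = 2))
#' @export
placeSites <- function(region, n = 125, urbanWeight = 0.9, seed = 1) {
  stopIfNot(methods::is(region, "SyntheticRegion"),
            "`region` must be a SyntheticRegion")
  if (n < 1) stop("placement error: n must be >= 1", call. = FALSE)
  stopIfNot(urbanWeight >= 0 && urbanWeight <= 1,
            "urbanWeight must lie in [0, 1]")
  lu <- region@landuse
  urb <- lu %in% match(c("residential", "commercial"), LANDUSE_CLASSES)
  dim(urb) <- dim(lu)
  # urbanWeight is the expected urban share of sites: the region's
  # site-suitability raster (urbanized cells, district centers within
  # commercial cores) carries a probability mass of urbanWeight, and all
  # cells share the remainder uniformly
  suit <- region@siteSuit
  if (!sum(suit)) suit <- urb * 1
  w <- if (sum(suit) > 0) urbanWeight * suit / sum(suit) else 0 * suit
  w <- w + (1 - urbanWeight) / length(urb)
  if (n > sum(w > 0)) {
    stop("placement error: n exceeds the number of available cells",
         call. = FALSE)
  }
  withSeed(seed, {
    idx <- sample.int(length(w), n, replace = FALSE, prob = w)
    nr <- nrow(lu)
    row <- ((idx - 1L) %% nr) + 1L
    col <- ((idx - 1L) %/% nr) + 1L
    x <- cellCenterX(col, region@cellSize)
    y <- cellCenterY(row, region@cellSize)
    third <- findInterval(x, c(-Inf, ncol(lu) * region@cellSize / 3,
                               2 * ncol(lu) * region@cellSize / 3))
    data.frame(id = sprintf("site_%04d", seq_len(n)), x = x, y = y,
               zone = c("incheon", "seoul", "gyeonggi")[third],
               row = row, col = col, stringsAsFactors = FALSE)
  })
}

#' Apply a climate-scenario perturbation
#'
#' Returns a copy of the region whose per-season temperature surfaces are
#' shifted by an additive offset (degC) and precipitation surfaces scaled by
#' a factor, emulating a future-climate projection. Land use, roads,
#' coastline, altitude and population rasters are untouched, matching the
#' land-use-held-fixed convention of scenario re-prediction.
#'
#' @param region a [SyntheticRegion-class].
#' @param deltas named list `season -> list(tempOffset = degC,
#'   precScale = factor)`; omitted seasons are unchanged.
#' @return perturbed [SyntheticRegion-class].
#' @examples
#' region <- generateRegion(regionConfig(width = 60, height = 60), seed = 1)
#' fut <- rcpPerturbation(region, list(winter = list(tempOffset = 2)))
#' @export
rcpPerturbation <- function(region, deltas) {
  stopIfNot(methods::is(region, "SyntheticRegion"),
            "`region` must be a SyntheticRegion")
  bad <- setdiff(names(deltas), SEASONS)
  if (length(bad)) {
    stop(sprintf("unknown season key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  out <- region
  for (s in names(deltas)) {
    d <- deltas[[s]]
    if (!is.null(d$tempOffset)) {
      out@climate[[s]]$temperature <- out@climate[[s]]$temperature + d$tempOffset
    }
    if (!is.null(d$precScale)) {
      out@climate[[s]]$precipitation <- out@climate[[s]]$precipitation * d$precScale
    }
  }
  out
}

#' Default future-climate scenario offsets
#'
#' Per-season temperature offsets (degC) and precipitation scalings for the
#' two bundled scenarios, loosely patterned on mid/high greenhouse-gas
#' trajectory projections for East Asia at the 2070 horizon: a moderate
#' scenario (`rcp45`) and a high-emission scenario (`rcp85`) with stronger
#' warming, wetter summers and drier falls/winters.
#'
#' @return named list `scenario -> season -> list(tempOffset, precScale)`.
#' @export
defaultScenarioDeltas <- function() {
  list(
    rcp45 = list(spring = list(tempOffset = 2.4, precScale = 1.05),
                 summer = list(tempOffset = 2.2, precScale = 1.08),
                 fall   = list(tempOffset = 2.5, precScale = 0.95),
                 winter = list(tempOffset = 2.8, precScale = 0.90)),
    rcp85 = list(spring = list(tempOffset = 3.3, precScale = 1.08),
                 summer = list(tempOffset = 3.2, precScale = 1.12),
                 fall   = list(tempOffset = 3.6, precScale = 0.92),
                 winter = list(tempOffset = 4.0, precScale = 0.85))
  )
}
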