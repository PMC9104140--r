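# Site-level buffer extraction. One membership rule is shared by every
# raster-based extraction: a cell belongs to the buffer iff its center lies
# within the closed disc around the site. Road length alone is computed by
# exact segment-circle clipping of the vector network.

#' Road length within a buffer
#'
#' Total length (m) of the road network intersected with the closed disc of
#' `radius` metres around `(x, y)`, by exact segment-circle clipping.
#'
#' @param x,y site coordinates in metres.
#' @param roads list of polyline coordinate matrices (or a
#'   [SyntheticRegion-class], whose roads are used).
#' @param radius buffer radius in metres (> 0).
#' @return length in metres; 0 for an empty network.
#' @examples
#' roadLengthInBuffer(0, 0, list(cbind(c(-1000, 1000), c(0, 0))), 200)
#' @export
roadLengthInBuffer <- function(x, y, roads, radius) {
  stopIfNot(radius > 0, "radius must be > 0")
  if (methods::is(roads, "SyntheticRegion")) roads <- roads@roads
  segs <- polylineSegments(roads)
  if (!nrow(segs)) return(0)
  chordLengthsInDisc(segs, x, y, radius)
}

# Sum over segments of |segment chord inside the disc|; vectorized.
chordLengthsInDisc <- function(segs, x, y, radius) {
  dx <- segs[, "x2"] - segs[, "x1"]
  dy <- segs[, "y2"] - segs[, "y1"]
  fx <- segs[, "x1"] - x
  fy <- segs[, "y1"] - y
  a <- dx * dx + dy * dy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - radius^2
  disc <- b * b - 4 * a * cc
  ok <- disc > 0 & a > 0
  if (!any(ok)) return(0)
  sq <- sqrt(disc[ok])
  t1 <- pmax(0, (-b[ok] - sq) / (2 * a[ok]))
  t2 <- pmin(1, (-b[ok] + sq) / (2 * a[ok]))
  sum(pmax(0, t2 - t1) * sqrt(a[ok]))
}

#' Land-use class area within a buffer
#'
#' Area (m^2) of cells of the given class whose centers lie within the
#' closed disc: `count * cellSize^2`.
#'
#' @param region a [SyntheticRegion-class].
#' @param class land-use class name.
#' @param x,y site coordinates (m).
#' @param radius buffer radius (m).
#' @return area in m^2.
#' @export
landuseAreaInBuffer <- function(region, class, x, y, radius) {
  stopIfNot(radius > 0, "radius must be > 0")
  if (!class %in% LANDUSE_CLASSES) {
    stop(sprintf("specification error: unknown land-use class '%s'", class),
         call. = FALSE)
  }
  lu <- region@landuse
  idx <- discCellIndex(x, y, radius, nrow(lu), ncol(lu), region@cellSize)
  sum(lu[idx] == match(class, LANDUSE_CLASSES)) * region@cellSize^2
}

#' Count density within a buffer
#'
#' Sum of per-cell counts over the disc divided by the disc area
#' (`nominal cells-in-disc * cellSize^2`, counting cells of the conceptual
#' unbounded grid so the denominator does not shrink at raster edges), in
#' counts per m^2.
#'
#' @param counts numeric matrix of non-negative per-cell counts, or the name
#'   of a region count raster (`popCount`, `housingCount`) with `region`.
#' @param region optional [SyntheticRegion-class] supplying geometry when
#'   `counts` is a name; required to resolve the cell size otherwise via
#'   `cellSize`.
#' @param x,y site coordinates (m).
#' @param radius buffer radius (m).
#' @param cellSize cell edge (m) when `counts` is a bare matrix.
#' @return density per m^2.
#' @export
densityInBuffer <- function(counts, x, y, radius, region = NULL,
                            cellSize = NULL) {
  if (is.character(counts)) {
    stopIfNot(!is.null(region), "a region is needed to resolve a named raster")
    counts <- slot(region, counts)
  }
  if (!is.null(region)) cellSize <- region@cellSize
  stopIfNot(!is.null(cellSize), "cellSize is required")
  stopIfNot(all(counts >= 0), "counts must be non-negative")
  nom <- discNominalCount(x, y, radius, cellSize)
  if (nom == 0) {
    stop("buffer radius below the raster resolution: no cell centers in disc",
         call. = FALSE)
  }
  idx <- discCellIndex(x, y, radius, nrow(counts), ncol(counts), cellSize)
  sum(counts[idx]) / (nom * cellSize^2)
}

#' Buffer mean of a climate (or any) raster
#'
#' Mean of the raster over cells whose centers lie within the closed disc.
#'
#' @param region a [SyntheticRegion-class].
#' @param variable `temperature`, `precipitation`, `windSpeed`, or
#'   `altitude`.
#' @param season season name for climate variables; ignored for altitude.
#' @param x,y site coordinates (m).
#' @param radius buffer radius (m).
#' @return mean value in the raster's units.
#' @export
climateMeanInBuffer <- function(region, variable, season = NULL, x, y, radius) {
  rast <- if (identical(variable, "altitude")) {
    region@altitude
  } else {
    stopIfNot(!is.null(season), "season is required for climate variables")
    climateRaster(region, variable, season)
  }
  idx <- discCellIndex(x, y, radius, nrow(rast), ncol(rast), region@cellSize)
  if (!length(idx)) {
    stop("buffer radius below the raster resolution: no cell centers in disc",
         call. = FALSE)
  }
  mean(rast[idx])
}

#' Distance to the coastline
#'
#' Euclidean distance (m) from a site to the nearest point of the coastline
#' polyline.
#'
#' @param x,y site coordinates (m).
#' @param coast two-column coordinate matrix, or a [SyntheticRegion-class].
#' @return distance in metres.
#' @export
distanceToCoast <- function(x, y, coast) {
  if (methods::is(coast, "SyntheticRegion")) coast <- coast@coastline
  segs <- polylineSegments(list(coast))
  if (!nrow(segs)) stop("empty coastline", call. = FALSE)
  pointSegmentDistance(x, y, segs)
}

# Dispatch a single (variable, radius, season) extraction at a site.
extractOne <- function(region, variable, x, y, radius, season = NULL,
                       specs = defaultVariableSpecs()) {
  row <- specs[specs$name == variable, ]
  if (!nrow(row)) {
    stop(sprintf("model specification error: unknown variable '%s'", variable),
         call. = FALSE)
  }
  switch(row$kind,
    length_sum  = roadLengthInBuffer(x, y, region@roads, radius),
    area_sum    = landuseAreaInBuffer(region, areaVariableClass(variable),
                                      x, y, radius),
    density     = densityInBuffer(if (variable == "population_density")
                                    "popCount" else "housingCount",
                                  x, y, radius, region = region),
    buffer_mean = climateMeanInBuffer(region, variable, season, x, y, radius),
    distance    = distanceToCoast(x, y, region@coastline),
    stop(sprintf("unknown extraction kind '%s'", row$kind), call. = FALSE)
  )
}

#' Build the covariate cube
#'
#' Extracts every requested variable at every candidate radius (and season,
#' for seasonal variables) for every site, into a long-format
#' [FeatureCube-class]. Sites placed by [placeSites()] sit on cell centers,
#' for which a fast shared-offset path is used; arbitrary coordinates fall
#' back to per-site scans under the identical disc-membership rule.
#'
#' @param region a [SyntheticRegion-class].
#' @param sites site data.frame (`id`, `x`, `y`).
#' @param specs variable catalogue from [defaultVariableSpecs()] (possibly
#'   subset).
#' @return a [FeatureCube-class].
#' @examples
#' region <- generateRegion(regionConfig(width = 60, height = 60), seed = 1)
#' sites <- placeSites(region, n = 5, seed = 2)
#' cube <- buildFeatureCube(region, sites,
#'                          specs = defaultVariableSpecs(radii = c(100, 300)))
#' head(cubeTable(cube))
#' @export
buildFeatureCube <- function(region, sites, specs = defaultVariableSpecs()) {
  stopIfNot(methods::is(region, "SyntheticRegion"),
            "`region` must be a SyntheticRegion")
  stopIfNot(nrow(specs) > 0, "specs must be non-empty")
  stopIfNot(all(c("id", "x", "y") %in% names(sites)), "sites need id, x, y")
  n <- nrow(sites)
  cs <- region@cellSize
  nr <- nrow(region@landuse); ncg <- ncol(region@landuse)

  onCenters <- all(abs(sites$x / cs - (floor(sites$x / cs) + 0.5)) < 1e-9) &&
    all(abs(sites$y / cs - (floor(sites$y / cs) + 0.5)) < 1e-9)
  siteRow <- rowOfY(sites$y, cs); siteCol <- colOfX(sites$x, cs)

  # rasters needed, keyed by variable (seasonal ones expand per season)
  rasterFor <- function(variable, season) {
    switch(specs$kind[specs$name == variable],
      area_sum = (region@landuse == match(areaVariableClass(variable),
                                          LANDUSE_CLASSES)) * 1,
      density = if (variable == "population_density") region@popCount
                else region@housingCount,
      buffer_mean = if (variable == "altitude") region@altitude
                    else climateRaster(region, variable, season),
      NULL)
  }

  allRadii <- sort(unique(unlist(specs$radii)))
  rows <- vector("list", 0L)
  addRows <- function(variable, radius, season, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      site = sites$id, variable = variable,
      radius = if (is.null(radius)) NA_real_ else radius,
      season = if (is.null(season)) NA_character_ else season,
      value = value, stringsAsFactors = FALSE)
  }

  # raster-based variables, one pass per radius
  rasterVars <- specs[specs$kind %in% c("area_sum", "density", "buffer_mean"), ]
  for (radius in allRadii) {
    if (onCenters) {
      off <- discOffsets(radius, cs)
      ri <- outer(siteRow, off$dy, "+")
      ci <- outer(siteCol, off$dx, "+")
      valid <- ri >= 1L & ri <= nr & ci >= 1L & ci <= ncg
      lin <- (ci - 1L) * nr + ri
      lin[!valid] <- 1L
      counts <- rowSums(valid)
      nominal <- rep(length(off$dy), n)
    } else {
      idxList <- lapply(seq_len(n), function(i)
        discCellIndex(sites$x[i], sites$y[i], radius, nr, ncg, cs))
      counts <- lengths(idxList)
      nominal <- vapply(seq_len(n), function(i)
        discNominalCount(sites$x[i], sites$y[i], radius, cs), numeric(1))
    }
    if (any(counts == 0) &&
        any(rasterVars$kind %in% c("density", "buffer_mean"))) {
      stop("buffer radius below the raster resolution: no cell centers in disc",
           call. = FALSE)
    }
    discSum <- function(rast) {
      if (onCenters) {
        v <- matrix(rast[lin], nrow = n)
        v[!valid] <- 0
        rowSums(v)
      } else {
        vapply(idxList, function(ix) sum(rast[ix]), numeric(1))
      }
    }
    for (j in seq_len(nrow(rasterVars))) {
      v <- rasterVars$name[j]
      if (!radius %in% rasterVars$radii[[j]]) next
      seasonsFor <- if (rasterVars$seasonal[j]) SEASONS else list(NULL)
      for (s in seasonsFor) {
        rast <- rasterFor(v, s)
        sums <- discSum(rast)
        value <- switch(rasterVars$kind[j],
          area_sum = sums * cs^2,
          density = sums / (nominal * cs^2),
          buffer_mean = sums / counts)
        addRows(v, radius, s, value)
      }
    }
  }

  # road length: exact vector clipping per (site, radius)
  if ("road_length" %in% specs$name) {
    segs <- polylineSegments(region@roads)
    rr <- specs$radii[[which(specs$name == "road_length")]]
    for (radius in rr) {
      value <- if (nrow(segs)) {
        vapply(seq_len(n), function(i)
          chordLengthsInDisc(segs, sites$x[i], sites$y[i], radius), numeric(1))
      } else rep(0, n)
      addRows("road_length", radius, NULL, value)
    }
  }

  # distance to coast: radius-free
  if ("distance_to_coast" %in% specs$name) {
    segsC <- polylineSegments(list(region@coastline))
    stopIfNot(nrow(segsC) > 0, "empty coastline")
    value <- vapply(seq_len(n), function(i)
      pointSegmentDistance(sites$x[i], sites$y[i], segsC), numeric(1))
    addRows("distance_to_coast", NULL, NULL, value)
  }

  tab <- do.call(rbind, rows)
  methods::new("FeatureCube", table = tab, sites = sites$id, specs = specs)
}

#' Extract one covariate vector from a cube
#'
#' @param cube a [FeatureCube-class].
#' @param variable variable name.
#' @param radius radius in metres (`NULL` for the distance variable).
#' @param season season name (`NULL` for static variables).
#' @return numeric vector named by site, in the cube's canonical site order.
#' @export
featureValues <- function(cube, variable, radius = NULL, season = NULL) {
  tab <- cube@table
  sel <- tab$variable == variable &
    (if (is.null(radius)) is.na(tab$radius) else
       !is.na(tab$radius) & tab$radius == radius) &
    (if (is.null(season)) is.na(tab$season) else
       !is.na(tab$season) & tab$season == season)
  sub <- tab[sel, ]
  if (!nrow(sub)) {
    stop(sprintf("no cube entries for %s (radius %s, season %s)", variable,
                 radius %||% "NA", season %||% "NA"), call. = FALSE)
  }
  stats::setNames(sub$value, sub$site)[cube@sites]
}
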