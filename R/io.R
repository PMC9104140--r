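# Text-based interchange: ESRI ASCII grids for rasters, GeoJSON for
# polylines, CSV for tables, JSON for models and reports. All planar
# coordinates; x origin at the region's west edge, y at its north edge.

#' Write / read an ESRI ASCII grid
#'
#' Plain-text raster interchange (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header, rows north to south). Values are
#' written with 17 significant digits so a round trip is exact.
#'
#' @param mat numeric matrix (row 1 = north).
#' @param path file path.
#' @param cellSize cell edge in metres.
#' @return `readAsciiGrid()` returns the matrix with attribute `cellSize`.
#' @export
writeAsciiGrid <- function(mat, path, cellSize) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(mat)),
               sprintf("nrows %d", nrow(mat)),
               "xllcorner 0", "yllcorner 0",
               sprintf("cellsize %.10g", cellSize),
               "NODATA_value -9999"), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(formatC(mat[i, ], format = "g", digits = 17),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  vals <- stats::setNames(vapply(hdr, `[`, character(1), 2),
                          tolower(vapply(hdr, `[`, character(1), 1)))
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  mat <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  attr(mat, "cellSize") <- as.numeric(vals[["cellsize"]])
  mat
}

#' Write / read polylines as GeoJSON
#'
#' A `FeatureCollection` of `LineString` features in planar metres.
#'
#' @param lines list of two-column coordinate matrices.
#' @param path file path.
#' @return `readGeoJSONLines()` returns the list of coordinate matrices.
#' @export
writeGeoJSONLines <- function(lines, path) {
  features <- lapply(seq_along(lines), function(i) {
    list(type = "Feature", properties = list(id = i),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(as.matrix(lines[[i]]), 1,
                                                    as.list, simplify = FALSE))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGeoJSONLines
#' @export
readGeoJSONLines <- function(path) {
  g <- jsonlite::read_json(path)
  lapply(g$features, function(f) {
    co <- f$geometry$coordinates
    m <- do.call(rbind, lapply(co, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("x", "y")
    m
  })
}

#' Export / import a synthetic region as text files
#'
#' Writes the land-use codes, altitude, population and housing counts and
#' the twelve climate rasters as ASCII grids, the roads and coastline as
#' GeoJSON, and the metadata (cell size, seed, class levels) as JSON.
#'
#' @param region a [SyntheticRegion-class].
#' @param dir output directory (created if needed).
#' @return `importRegion()` reconstructs the [SyntheticRegion-class].
#' @export
exportRegion <- function(region, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- region@cellSize
  lu <- region@landuse; attributes(lu) <- list(dim = dim(lu))
  writeAsciiGrid(lu, file.path(dir, "landuse.asc"), cs)
  writeAsciiGrid(region@altitude, file.path(dir, "altitude.asc"), cs)
  writeAsciiGrid(region@popCount, file.path(dir, "pop_count.asc"), cs)
  writeAsciiGrid(region@housingCount, file.path(dir, "housing_count.asc"), cs)
  writeAsciiGrid(region@siteSuit, file.path(dir, "site_suitability.asc"), cs)
  for (s in SEASONS) {
    for (v in c("temperature", "precipitation", "windSpeed")) {
      writeAsciiGrid(region@climate[[s]][[v]],
                     file.path(dir, sprintf("climate_%s_%s.asc", v, s)), cs)
    }
  }
  writeGeoJSONLines(region@roads, file.path(dir, "roads.geojson"))
  writeGeoJSONLines(list(region@coastline),
                    file.path(dir, "coastline.geojson"))
  jsonlite::write_json(list(cellSize = cs, seed = region@seed,
                            landuseLevels = LANDUSE_CLASSES),
                       file.path(dir, "region_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname exportRegion
#' @export
importRegion <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "region_meta.json"),
                              simplifyVector = TRUE)
  rd <- function(f) {
    m <- readAsciiGrid(file.path(dir, f)); attr(m, "cellSize") <- NULL; m
  }
  lu <- rd("landuse.asc")
  storage.mode(lu) <- "integer"
  attr(lu, "levels") <- meta$landuseLevels
  climate <- stats::setNames(lapply(SEASONS, function(s) {
    list(temperature = rd(sprintf("climate_temperature_%s.asc", s)),
         precipitation = rd(sprintf("climate_precipitation_%s.asc", s)),
         windSpeed = rd(sprintf("climate_windSpeed_%s.asc", s)))
  }), SEASONS)
  methods::new("SyntheticRegion", cellSize = meta$cellSize, landuse = lu,
               roads = readGeoJSONLines(file.path(dir, "roads.geojson")),
               coastline = readGeoJSONLines(
                 file.path(dir, "coastline.geojson"))[[1]],
               altitude = rd("altitude.asc"),
               popCount = rd("pop_count.asc"),
               housingCount = rd("housing_count.asc"),
               siteSuit = rd("site_suitability.asc"),
               climate = climate, seed = as.integer(meta$seed),
               config = list())
}

#' Serialize models to / from JSON
#'
#' Writes a named list of [TruthModel-class] or [LURModel-class] objects
#' (intercepts and coefficients in ppm; CV RMSE in ppb).
#'
#' @param models named list of models.
#' @param path file path.
#' @return `readTruthModels()` / `readLURModels()` reconstruct the list.
#' @export
writeModelsJSON <- function(models, path) {
  ser <- lapply(models, function(m) {
    base <- list(season = m@season, intercept = m@intercept,
                 terms = m@terms)
    if (methods::is(m, "TruthModel")) {
      c(base, list(kind = "truth", noiseSd = m@noiseSd))
    } else {
      c(base, list(kind = "lur", nSites = m@nSites, adjR2 = m@adjR2,
                   cvRMSE = m@cvRMSE, criteria = m@criteria))
    }
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writeModelsJSON
#' @export
readTruthModels <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  lapply(raw, function(m) {
    methods::new("TruthModel", season = m$season, intercept = m$intercept,
                 terms = as.data.frame(m$terms), noiseSd = m$noiseSd)
  })
}

#' @rdname writeModelsJSON
#' @export
readLURModels <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  lapply(raw, function(m) {
    methods::new("LURModel", season = m$season, intercept = m$intercept,
                 terms = as.data.frame(m$terms), nSites = as.integer(m$nSites),
                 adjR2 = m$adjR2, cvRMSE = m$cvRMSE,
                 criteria = as.list(m$criteria),
                 trace = data.frame(iteration = integer(0),
                                    action = character(0),
                                    variable = character(0), p = numeric(0)))
  })
}

#' Write a feature cube as long-format CSV
#'
#' Columns `site`, `variable`, `radius`, `season`, `value`.
#'
#' @param cube a [FeatureCube-class].
#' @param path file path.
#' @return `readFeatureCube()` reconstructs the cube (catalogue defaults
#'   are re-attached by variable name).
#' @export
writeFeatureCube <- function(cube, path) {
  utils::write.csv(cube@table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCube
#' @export
readFeatureCube <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$season <- as.character(tab$season)
  tab$season[tab$season == ""] <- NA_character_
  methods::new("FeatureCube", table = tab, sites = unique(tab$site),
               specs = defaultVariableSpecs())
}

# Write every bundle artifact under `dir`.
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exportRegion(bundle$region, file.path(dir, "region"))
  utils::write.csv(bundle$sites[, c("id", "x", "y", "zone")],
                   file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(bundle$concentrations,
                   file.path(dir, "concentrations.csv"), row.names = FALSE)
  writeFeatureCube(bundle$cube, file.path(dir, "feature_cube.csv"))
  writeModelsJSON(bundle$config$truth, file.path(dir, "truth_models.json"))
  writeModelsJSON(bundle$models, file.path(dir, "lur_models.json"))
  jsonlite::write_json(
    list(status = bundle$screening@status, buffers = bundle$screening@buffers,
         thresholds = as.list(bundle$screening@thresholds)),
    file.path(dir, "screening.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  for (s in names(bundle$surfaces)) {
    writeAsciiGrid(surfaceValues(bundle$surfaces[[s]]),
                   file.path(dir, sprintf("surface_present_%s.asc", s)),
                   bundle$region@cellSize)
  }
  for (nm in names(bundle$scenarios)) {
    for (s in names(bundle$scenarios[[nm]]$surfaces)) {
      writeAsciiGrid(surfaceValues(bundle$scenarios[[nm]]$surfaces[[s]]),
                     file.path(dir, sprintf("surface_%s_%s.asc", nm, s)),
                     bundle$region@cellSize)
    }
  }
  utils::write.csv(bundle$levels, file.path(dir, "level_fractions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = bundle$config$seed, seeds = bundle$seeds),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
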