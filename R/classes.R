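#' @import methods
NULL

#' Synthetic metropolitan region
#'
#' An S4 container for the toy planar geography used throughout the package:
#' a categorical land-use raster, a road polyline network, a coastline,
#' altitude, population and housing count rasters, and per-season climate
#' rasters (temperature, precipitation, wind speed), all on a shared
#' `cellSize`-metre grid. Coordinates are planar metres; cell `(1, 1)` is the
#' top-left cell, `x = (col - 0.5) * cellSize`, `y = (row - 0.5) * cellSize`.
#'
#' @slot cellSize grid resolution in metres (default 30).
#' @slot landuse integer matrix of land-use codes; `levels` attribute holds
#'   the class names (`governmental`, `commercial`, `residential`,
#'   `industrial`, `open_space`, `other`).
#' @slot roads list of two-column coordinate matrices (polylines, metres).
#' @slot coastline two-column coordinate matrix (polyline, metres).
#' @slot altitude numeric matrix (metres).
#' @slot popCount,housingCount numeric matrices of per-cell counts.
#' @slot climate named list `season -> list(temperature, precipitation,
#'   windSpeed)` of numeric matrices (degC, mm, m/s).
#' @slot siteSuit numeric matrix of site-placement suitability (monitoring
#'   networks favour urbanized cells, and district centers within
#'   commercial cores).
#' @slot seed integer seed the region was generated from.
#' @slot config the region configuration list used by [generateRegion()].
#' @export
setClass("SyntheticRegion",
  representation(
    cellSize = "numeric",
    landuse = "matrix",
    roads = "list",
    coastline = "matrix",
    altitude = "matrix",
    popCount = "matrix",
    housingCount = "matrix",
    climate = "list",
    siteSuit = "matrix",
    seed = "integer",
    config = "list"
  )
)

setValidity("SyntheticRegion", function(object) {
  msgs <- character(0)
  dm <- dim(object@landuse)
  if (object@cellSize <= 0) msgs <- c(msgs, "cellSize must be positive")
  for (nm in c("altitude", "popCount", "housingCount", "siteSuit")) {
    if (!identical(dim(slot(object, nm)), dm)) {
      msgs <- c(msgs, sprintf("raster '%s' does not match land-use shape", nm))
    }
  }
  if (!setequal(names(object@climate), SEASONS)) {
    msgs <- c(msgs, "climate must hold exactly the four seasons")
  } else {
    for (s in SEASONS) {
      for (v in c("temperature", "precipitation", "windSpeed")) {
        m <- object@climate[[s]][[v]]
        if (is.null(m) || !identical(dim(m), dm)) {
          msgs <- c(msgs, sprintf("climate raster %s/%s missing or mis-shaped", s, v))
        }
      }
    }
  }
  lv <- attr(object@landuse, "levels")
  if (is.null(lv) || !all(object@landuse %in% seq_along(lv))) {
    msgs <- c(msgs, "landuse codes must index its levels attribute")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth seasonal concentration model
#'
#' The data-generating linear model used by [simulateConcentrations()]:
#' NO2 (ppb) = 1000 * (intercept + sum coefficient * covariate) + noise,
#' with the intercept and coefficients in ppm per covariate unit and the
#' Gaussian noise standard deviation in ppb.
#'
#' @slot season one of `spring`, `summer`, `fall`, `winter`.
#' @slot intercept intercept in ppm.
#' @slot terms data.frame with columns `variable`, `radius` (m),
#'   `coefficient` (ppm per covariate unit).
#' @slot noiseSd Gaussian noise sd in ppb.
#' @export
setClass("TruthModel",
  representation(season = "character", intercept = "numeric",
                 terms = "data.frame", noiseSd = "numeric")
)

setValidity("TruthModel", function(object) {
  msgs <- character(0)
  if (!object@season %in% SEASONS) msgs <- c(msgs, "unknown season")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  need <- c("variable", "radius", "coefficient")
  if (!all(need %in% names(object@terms))) {
    msgs <- c(msgs, "terms needs columns variable, radius, coefficient")
  } else if (nrow(object@terms)) {
    r <- object@terms$radius
    if (!all(is.na(r) | (r >= 100 & r <= 1000))) {
      msgs <- c(msgs, "term radii must lie in [100, 1000] m")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Buffer-extracted covariate cube
#'
#' Long-format store of covariate values indexed by (site, variable, buffer
#' radius, season). Static variables carry `season = NA`; the distance
#' variable carries `radius = NA`.
#'
#' @slot table data.frame with columns `site`, `variable`, `radius`,
#'   `season`, `value`.
#' @slot sites character vector of site ids in canonical order.
#' @slot specs the variable-specification data.frame the cube was built from.
#' @export
setClass("FeatureCube",
  representation(table = "data.frame", sites = "character", specs = "data.frame")
)

setValidity("FeatureCube", function(object) {
  need <- c("site", "variable", "radius", "season", "value")
  if (!all(need %in% names(object@table))) {
    return("table needs columns site, variable, radius, season, value")
  }
  if (anyNA(object@table$value)) return("cube values must not be missing")
  if (!all(object@table$site %in% object@sites)) {
    return("table contains sites absent from the site register")
  }
  TRUE
})

#' Variable screening report
#'
#' Records, for every catalogued variable, the optimum buffer per
#' (variable, season), the correlation profile over candidate radii, and the
#' kept/dropped status after the response-correlation and collinearity
#' screens (and, once models are fitted, the stepwise outcome).
#'
#' @slot buffers data.frame `variable`, `season`, `radius`, `r` at the
#'   chosen radius.
#' @slot status data.frame `variable`, `status`, `with` (collinear partner
#'   or `NA`), `rResponse` (max-over-seasons |r| vs concentration),
#'   `maxPairR` (max pairwise |r| among screened variables).
#' @slot profiles named list `variable -> data.frame(season, radius, r)`.
#' @slot thresholds numeric: `low` (response screen), `high` (collinearity).
#' @export
setClass("ScreeningReport",
  representation(buffers = "data.frame", status = "data.frame",
                 profiles = "list", thresholds = "numeric")
)

setValidity("ScreeningReport", function(object) {
  ok <- c("kept", "dropped_low_response_corr", "dropped_collinear",
          "dropped_stepwise")
  if (!all(object@status$status %in% ok)) return("unknown screening status")
  if (anyDuplicated(object@status$variable)) {
    return("every variable must have exactly one status")
  }
  TRUE
})

#' Fitted seasonal land-use-regression model
#'
#' @slot season season label.
#' @slot intercept intercept in ppm.
#' @slot terms data.frame `variable`, `radius`, `coefficient` (ppm per unit),
#'   `se` (ppm per unit), `p`.
#' @slot nSites number of sites used in the fit.
#' @slot adjR2 adjusted R-squared from the full-data fit.
#' @slot cvRMSE pooled k-fold cross-validation RMSE in ppb.
#' @slot criteria list with `pEnter`, `pRemove`, `k`, `cvSeed`.
#' @slot trace data.frame step trace (`iteration`, `action`, `variable`, `p`).
#' @export
setClass("LURModel",
  representation(season = "character", intercept = "numeric",
                 terms = "data.frame", nSites = "integer",
                 adjR2 = "numeric", cvRMSE = "numeric",
                 criteria = "list", trace = "data.frame")
)

setValidity("LURModel", function(object) {
  msgs <- character(0)
  if (!object@season %in% SEASONS) msgs <- c(msgs, "unknown season")
  if (nrow(object@terms) && !all(object@terms$p >= 0 & object@terms$p <= 1)) {
    msgs <- c(msgs, "term p-values must lie in [0, 1]")
  }
  if (length(object@cvRMSE) && !is.na(object@cvRMSE) && object@cvRMSE < 0) {
    msgs <- c(msgs, "cvRMSE must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Predicted concentration surface
#'
#' @slot values numeric matrix of NO2 concentrations in ppb (clipped at 0).
#' @slot season season label (or `annual`).
#' @slot scenario one of `present`, `rcp45`, `rcp85` (free-form allowed).
#' @slot clippedCells number of cells clipped up to zero.
#' @slot provenance list (model season, criteria, region seed).
#' @export
setClass("ConcentrationSurface",
  representation(values = "matrix", season = "character",
                 scenario = "character", clippedCells = "integer",
                 provenance = "list")
)

setValidity("ConcentrationSurface", function(object) {
  if (any(object@values < 0)) return("surface values must be >= 0 after clipping")
  TRUE
})

# ---- generics & accessors ---------------------------------------------------

#' Region accessors
#'
#' Small accessor family for [SyntheticRegion-class] objects: grid resolution,
#' dimensions, land-use factor matrix, roads, coastline and climate rasters.
#'
#' @param object,region a `SyntheticRegion`.
#' @param variable climate variable: `temperature`, `precipitation`,
#'   `windSpeed`.
#' @param season one of `spring`, `summer`, `fall`, `winter`.
#' @return `cellSize()` and `regionDim()` return numerics; `landuse()` an
#'   integer matrix with a `levels` attribute; `climateRaster()` a numeric
#'   matrix; `roads()` a list of coordinate matrices.
#' @name region-accessors
NULL

#' @rdname region-accessors
#' @export
setGeneric("cellSize", function(object) standardGeneric("cellSize"))
#' @rdname region-accessors
#' @export
setMethod("cellSize", "SyntheticRegion", function(object) object@cellSize)

#' @rdname region-accessors
#' @export
setGeneric("regionDim", function(object) standardGeneric("regionDim"))
#' @rdname region-accessors
#' @export
setMethod("regionDim", "SyntheticRegion", function(object) dim(object@landuse))

#' @rdname region-accessors
#' @export
setGeneric("landuse", function(object) standardGeneric("landuse"))
#' @rdname region-accessors
#' @export
setMethod("landuse", "SyntheticRegion", function(object) object@landuse)

#' @rdname region-accessors
#' @export
setGeneric("roads", function(object) standardGeneric("roads"))
#' @rdname region-accessors
#' @export
setMethod("roads", "SyntheticRegion", function(object) object@roads)

#' @rdname region-accessors
#' @export
setGeneric("coastline", function(object) standardGeneric("coastline"))
#' @rdname region-accessors
#' @export
setMethod("coastline", "SyntheticRegion", function(object) object@coastline)

#' @rdname region-accessors
#' @export
climateRaster <- function(region, variable, season) {
  stopIfNot(methods::is(region, "SyntheticRegion"), "`region` must be a SyntheticRegion")
  stopIfNot(season %in% SEASONS, sprintf("unknown season '%s'", season))
  if (identical(variable, "wind_speed")) variable <- "windSpeed"
  stopIfNot(variable %in% c("temperature", "precipitation", "windSpeed"),
            sprintf("unknown climate variable '%s'", variable))
  region@climate[[season]][[variable]]
}

#' Model accessors
#'
#' @param object a [LURModel-class] or [TruthModel-class].
#' @return `modelTerms()` the term data.frame; `modelSeason()` the season;
#'   `adjR2()` and `cvRMSE()` the validation metrics of a fitted model.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("modelTerms", function(object) standardGeneric("modelTerms"))
#' @rdname model-accessors
#' @export
setMethod("modelTerms", "LURModel", function(object) object@terms)
#' @rdname model-accessors
#' @export
setMethod("modelTerms", "TruthModel", function(object) object@terms)

#' @rdname model-accessors
#' @export
setGeneric("modelSeason", function(object) standardGeneric("modelSeason"))
#' @rdname model-accessors
#' @export
setMethod("modelSeason", "LURModel", function(object) object@season)
#' @rdname model-accessors
#' @export
setMethod("modelSeason", "TruthModel", function(object) object@season)

#' @rdname model-accessors
#' @export
setGeneric("adjR2", function(object) standardGeneric("adjR2"))
#' @rdname model-accessors
#' @export
setMethod("adjR2", "LURModel", function(object) object@adjR2)

#' @rdname model-accessors
#' @export
setGeneric("cvRMSE", function(object) standardGeneric("cvRMSE"))
#' @rdname model-accessors
#' @export
setMethod("cvRMSE", "LURModel", function(object) object@cvRMSE)

#' Cube and surface accessors
#'
#' @param object a [FeatureCube-class] or [ConcentrationSurface-class].
#' @return `cubeTable()` the long data.frame; `cubeSites()` the site ids;
#'   `surfaceValues()` the ppb matrix; `surfaceSeason()`/`surfaceScenario()`
#'   the labels.
#' @name cube-accessors
NULL

#' @rdname cube-accessors
#' @export
setGeneric("cubeTable", function(object) standardGeneric("cubeTable"))
#' @rdname cube-accessors
#' @export
setMethod("cubeTable", "FeatureCube", function(object) object@table)

#' @rdname cube-accessors
#' @export
setGeneric("cubeSites", function(object) standardGeneric("cubeSites"))
#' @rdname cube-accessors
#' @export
setMethod("cubeSites", "FeatureCube", function(object) object@sites)

#' @rdname cube-accessors
#' @export
setGeneric("surfaceValues", function(object) standardGeneric("surfaceValues"))
#' @rdname cube-accessors
#' @export
setMethod("surfaceValues", "ConcentrationSurface", function(object) object@values)

#' @rdname cube-accessors
#' @export
setGeneric("surfaceSeason", function(object) standardGeneric("surfaceSeason"))
#' @rdname cube-accessors
#' @export
setMethod("surfaceSeason", "ConcentrationSurface", function(object) object@season)

#' @rdname cube-accessors
#' @export
setGeneric("surfaceScenario", function(object) standardGeneric("surfaceScenario"))
#' @rdname cube-accessors
#' @export
setMethod("surfaceScenario", "ConcentrationSurface",
          function(object) object@scenario)

# ---- show methods -----------------------------------------------------------

setMethod("show", "SyntheticRegion", function(object) {
  dm <- dim(object@landuse)
  lv <- attr(object@landuse, "levels")
  cnt <- tabulate(object@landuse, nbins = length(lv))
  cat(sprintf("SyntheticRegion: %d x %d cells at %g m (%.1f x %.1f km), seed %d\n",
              dm[1], dm[2], object@cellSize,
              dm[2] * object@cellSize / 1000, dm[1] * object@cellSize / 1000,
              object@seed))
  cat("  land use: ",
      paste(sprintf("%s %.1f%%", lv, 100 * cnt / sum(cnt)), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  roads: %d polylines, %.1f km total\n", length(object@roads),
              sum(segmentLengths(polylineSegments(object@roads))) / 1000))
})

setMethod("show", "TruthModel", function(object) {
  cat(sprintf("TruthModel (%s): intercept %.4g ppm, noise sd %.2f ppb\n",
              object@season, object@intercept, object@noiseSd))
  if (nrow(object@terms)) {
    for (i in seq_len(nrow(object@terms))) {
      cat(sprintf("  %-18s @ %4.0f m  coef %.3g\n", object@terms$variable[i],
                  object@terms$radius[i], object@terms$coefficient[i]))
    }
  }
})

setMethod("show", "FeatureCube", function(object) {
  cat(sprintf("FeatureCube: %d sites x %d variables, %d values\n",
              length(object@sites), length(unique(object@table$variable)),
              nrow(object@table)))
})

setMethod("show", "ScreeningReport", function(object) {
  cat("ScreeningReport (|r| thresholds: response >=", object@thresholds[["low"]],
      ", pairwise <=", object@thresholds[["high"]], ")\n")
  st <- object@status
  for (i in seq_len(nrow(st))) {
    extra <- if (!is.na(st$with[i])) sprintf(" (with %s)", st$with[i]) else ""
    cat(sprintf("  %-20s %-26s |r|=%.2f%s\n", st$variable[i], st$status[i],
                st$rResponse[i], extra))
  }
})

setMethod("show", "LURModel", function(object) {
  cat(sprintf("LURModel (%s): n=%d, adj R2 = %.3f, CV RMSE = %.2f ppb\n",
              object@season, object@nSites, object@adjR2, object@cvRMSE))
  cat(sprintf("  constant  %.4g ppm\n", object@intercept))
  if (nrow(object@terms)) {
    for (i in seq_len(nrow(object@terms))) {
      cat(sprintf("  %-18s @ %4.0f m  coef %.3g  (p = %.3g)\n",
                  object@terms$variable[i], object@terms$radius[i],
                  object@terms$coefficient[i], object@terms$p[i]))
    }
  }
})

setMethod("show", "ConcentrationSurface", function(object) {
  cat(sprintf("ConcentrationSurface (%s, %s): mean %.1f ppb, range [%.1f, %.1f], %d cells clipped\n",
              object@season, object@scenario, mean(object@values),
              min(object@values), max(object@values), object@clippedCells))
})

segmentLengths <- function(segs) {
  if (!nrow(segs)) return(numeric(0))
  sqrt((segs[, "x2"] - segs[, "x1"])^2 + (segs[, "y2"] - segs[, "y1"])^2)
}
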