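#' Predictor variable catalogue
#'
#' The default catalogue of buffer-based predictor variables: road length
#' (traffic), the five land-use class areas, population and housing density,
#' the three seasonal climate variables, altitude and distance to coast.
#' Each row records the variable's extraction kind (`length_sum`,
#' `area_sum`, `density`, `buffer_mean`, `distance`), whether it is seasonal,
#' and its candidate buffer radii (100-1000 m in 100 m steps; the distance
#' variable has none).
#'
#' @param radii candidate buffer radii in metres.
#' @return data.frame with columns `name`, `category`, `kind`, `seasonal`,
#'   and a list-column `radii`.
#' @examples
#' defaultVariableSpecs()[, 1:4]
#' @export
defaultVariableSpecs <- function(radii = seq(100, 1000, by = 100)) {
  spec <- function(name, category, kind, seasonal, rr = radii) {
    data.frame(name = name, category = category, kind = kind,
               seasonal = seasonal, stringsAsFactors = FALSE)
  }
  out <- rbind(
    spec("road_length",       "traffic",    "length_sum",  FALSE),
    spec("governmental_area", "landuse",    "area_sum",    FALSE),
    spec("commercial_area",   "landuse",    "area_sum",    FALSE),
    spec("residential_area",  "landuse",    "area_sum",    FALSE),
    spec("industrial_area",   "landuse",    "area_sum",    FALSE),
    spec("open_space_area",   "landuse",    "area_sum",    FALSE),
    spec("population_density","population", "density",     FALSE),
    spec("housing_density",   "population", "density",     FALSE),
    spec("temperature",       "climate",    "buffer_mean", TRUE),
    spec("precipitation",     "climate",    "buffer_mean", TRUE),
    spec("wind_speed",        "climate",    "buffer_mean", TRUE),
    spec("altitude",          "other",      "buffer_mean", FALSE),
    spec("distance_to_coast", "other",      "distance",    FALSE)
  )
  out$radii <- rep(list(radii), nrow(out))
  out$radii[out$kind == "distance"] <- list(numeric(0))
  out
}

# land-use class behind each area variable
areaVariableClass <- function(variable) {
  map <- c(governmental_area = "governmental", commercial_area = "commercial",
           residential_area = "residential", industrial_area = "industrial",
           open_space_area = "open_space")
  unname(map[variable])
}

#' Built-in seasonal ground-truth models
#'
#' The four seasonal truth models the synthetic region is simulated from.
#' Intercepts and coefficients are in ppm (per covariate unit), so that a
#' site's concentration in ppb is `1000 * (intercept + sum(coef * x))` plus
#' Gaussian noise; the default noise standard deviations (5.1, 3.4, 5.1 and
#' 4.3 ppb for spring, summer, fall, winter) equal the cross-validated RMSE
#' the models are expected to reproduce. Term buffers: road length 200 m,
#' commercial area 100 m, residential area 1000 m, temperature 400 m
#' (`tempBuffer`; fall and winter default to a carry-forward of the summer
#' buffer), precipitation 100 m.
#'
#' Commercial area carries no effect in spring and summer, temperature none
#' in spring, and precipitation none in summer and winter; those terms are
#' absent rather than zero-coefficient.
#'
#' @param noiseSd named numeric, per-season noise sd in ppb. A single value
#'   is recycled to all seasons.
#' @param tempBuffer named numeric, per-season temperature buffer radius (m)
#'   for the seasons carrying a temperature effect.
#' @return named list of [TruthModel-class] objects (spring, summer, fall,
#'   winter).
#' @examples
#' defaultTruthModels()$winter
#' @export
defaultTruthModels <- function(noiseSd = c(spring = 5.1, summer = 3.4,
                                           fall = 5.1, winter = 4.3),
                               tempBuffer = c(summer = 400, fall = 400,
                                              winter = 400)) {
  if (length(noiseSd) == 1L && is.null(names(noiseSd))) {
    noiseSd <- stats::setNames(rep(noiseSd, 4), SEASONS)
  }
  term <- function(variable, radius, coefficient) {
    data.frame(variable = variable, radius = radius,
               coefficient = coefficient, stringsAsFactors = FALSE)
  }
  mk <- function(season, intercept, terms) {
    methods::new("TruthModel", season = season, intercept = intercept,
                 terms = terms, noiseSd = unname(noiseSd[[season]]))
  }
  list(
    spring = mk("spring", 0.023, rbind(
      term("road_length", 200, 5.9e-5),
      term("residential_area", 1000, 3e-7),
      term("precipitation", 100, 1.8e-5)
    )),
    summer = mk("summer", 0.015, rbind(
      term("road_length", 200, 5.5e-5),
      term("residential_area", 1000, 1.8e-7),
      term("temperature", unname(tempBuffer[["summer"]]), 3.3e-5)
    )),
    fall = mk("fall", 0.025, rbind(
      term("road_length", 200, 3.7e-5),
      term("commercial_area", 100, 1.4e-7),
      term("residential_area", 1000, 1.7e-7),
      term("temperature", unname(tempBuffer[["fall"]]), 2.6e-5),
      term("precipitation", 100, 2.8e-5)
    )),
    winter = mk("winter", 0.031, rbind(
      term("road_length", 200, 4.3e-5),
      term("commercial_area", 100, 1.6e-7),
      term("residential_area", 1000, 3.1e-7),
      term("temperature", unname(tempBuffer[["winter"]]), 3.3e-5)
    ))
  )
}
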