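# Grid spatialization of fitted models, health-threshold classification and
# present-vs-future scenario comparison.

#' Predict a concentration surface on the full grid
#'
#' Applies a fitted (or truth) seasonal model cellwise:
#' `1000 * (intercept + sum coefficient * focal covariate)` ppb, with
#' negative cells clipped to 0 and counted.
#'
#' @param model a [LURModel-class] or [TruthModel-class].
#' @param region a [SyntheticRegion-class].
#' @param scenario scenario label stored on the surface (default
#'   `"present"`).
#' @return a [ConcentrationSurface-class].
#' @examples
#' region <- generateRegion(regionConfig(width = 60, height = 60), seed = 1)
#' surf <- predictGrid(defaultTruthModels()$winter, region)
#' surf
#' @export
predictGrid <- function(model, region, scenario = "present") {
  stopIfNot(methods::is(model, "LURModel") || methods::is(model, "TruthModel"),
            "`model` must be a LURModel or TruthModel")
  terms <- modelTerms(model)
  season <- modelSeason(model)
  vals <- matrix(1000 * model@intercept,
                 nrow(region@landuse), ncol(region@landuse))
  if (nrow(terms)) {
    ff <- focalFeatures(region,
                        data.frame(variable = terms$variable,
                                   radius = terms$radius,
                                   stringsAsFactors = FALSE),
                        season = season)
    specs <- defaultVariableSpecs()
    for (i in seq_len(nrow(terms))) {
      v <- terms$variable[i]
      key <- if (isTRUE(specs$seasonal[match(v, specs$name)])) {
        sprintf("%s@%g@%s", v, terms$radius[i], season)
      } else if (identical(specs$kind[match(v, specs$name)], "distance")) v
      else sprintf("%s@%g", v, terms$radius[i])
      if (is.null(ff[[key]])) {
        stop(sprintf("prediction error: missing covariate raster for '%s'", v),
             call. = FALSE)
      }
      vals <- vals + 1000 * terms$coefficient[i] * ff[[key]]
    }
  }
  clipped <- sum(vals < 0)
  vals[vals < 0] <- 0
  methods::new("ConcentrationSurface", values = vals, season = season,
               scenario = scenario, clippedCells = as.integer(clipped),
               provenance = list(season = season, regionSeed = region@seed))
}

#' Classify a surface into health-threshold levels
#'
#' Low: below the first threshold; medium: between the thresholds,
#' inclusive at both ends; high: above the second threshold. Defaults to
#' the 30/40 ppb bands around the ~30 ppb annual NO2 guideline, so a cell
#' at exactly 30 or exactly 40 ppb is medium.
#'
#' @param surface a [ConcentrationSurface-class] (or bare ppb matrix).
#' @param thresholds increasing pair of ppb thresholds, default `c(30, 40)`.
#' @return list with `summary` (data.frame `season`, `scenario`, `low`,
#'   `medium`, `high` as area fractions) and `levels` (integer matrix,
#'   1 = low, 2 = medium, 3 = high).
#' @examples
#' classifyLevels(matrix(c(25, 35, 45, 40), 2))$summary
#' @export
classifyLevels <- function(surface, thresholds = c(30, 40)) {
  stopIfNot(length(thresholds) == 2 && thresholds[1] < thresholds[2] &&
              thresholds[1] > 0, "thresholds must be positive and ordered")
  vals <- if (methods::is(surface, "ConcentrationSurface"))
    surface@values else surface
  lev <- matrix(2L, nrow(vals), ncol(vals))
  lev[vals < thresholds[1]] <- 1L
  lev[vals > thresholds[2]] <- 3L
  n <- length(lev)
  summary <- data.frame(
    season = if (methods::is(surface, "ConcentrationSurface"))
      surface@season else NA_character_,
    scenario = if (methods::is(surface, "ConcentrationSurface"))
      surface@scenario else NA_character_,
    low = sum(lev == 1L) / n, medium = sum(lev == 2L) / n,
    high = sum(lev == 3L) / n, stringsAsFactors = FALSE)
  list(summary = summary, levels = lev)
}

#' Annual aggregation of four seasonal surfaces
#'
#' The annual surface is the cellwise mean of the four seasonal surfaces of
#' one scenario; level summaries are produced for each season and the
#' annual mean.
#'
#' @param surfaces named list of four [ConcentrationSurface-class] objects
#'   (spring, summer, fall, winter), same scenario.
#' @param thresholds passed to [classifyLevels()].
#' @return list with `annual` (a [ConcentrationSurface-class]) and
#'   `summary` (five-row data.frame: four seasons plus `annual`).
#' @export
seasonalAnnual <- function(surfaces, thresholds = c(30, 40)) {
  missing <- setdiff(SEASONS, names(surfaces))
  if (length(missing)) {
    stop(sprintf("aggregation error: missing season(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  scen <- unique(vapply(surfaces[SEASONS], surfaceScenario, character(1)))
  stopIfNot(length(scen) == 1, "all four surfaces must share one scenario")
  vals <- Reduce(`+`, lapply(surfaces[SEASONS], surfaceValues)) / 4
  annual <- methods::new("ConcentrationSurface", values = vals,
                         season = "annual", scenario = scen,
                         clippedCells = 0L,
                         provenance = list(aggregation = "mean of seasons"))
  summary <- do.call(rbind, c(
    lapply(SEASONS, function(s)
      classifyLevels(surfaces[[s]], thresholds)$summary),
    list(classifyLevels(annual, thresholds)$summary)))
  list(annual = annual, summary = summary)
}

#' Compare present and future-scenario predictions
#'
#' Re-predicts each seasonal model on a climate-perturbed copy of the
#' region and differences the surfaces. The future region must differ from
#' the present only in its climate rasters (land use held fixed); any other
#' difference is a scenario-contract violation. Because the models are
#' linear and non-climate covariates are unchanged, the delta surface
#' carries climate-term contributions only.
#'
#' @param models named list of seasonal [LURModel-class] /
#'   [TruthModel-class] objects.
#' @param present,future [SyntheticRegion-class] pair (e.g. `future` from
#'   [rcpPerturbation()]).
#' @param scenario label for the future predictions (default `"future"`).
#' @param thresholds passed to [classifyLevels()].
#' @return list with `present`, `future` (surface lists), `delta` (named
#'   list of matrices, future minus present, ppb), and `summary`
#'   (level fractions for both scenario labels, seasons plus annual when
#'   all four seasons are present).
#' @export
scenarioCompare <- function(models, present, future, scenario = "future",
                            thresholds = c(30, 40)) {
  if (!identical(present@landuse, future@landuse) ||
      !identical(present@roads, future@roads) ||
      !identical(present@coastline, future@coastline) ||
      !identical(present@altitude, future@altitude) ||
      !identical(present@popCount, future@popCount) ||
      !identical(present@housingCount, future@housingCount)) {
    stop("scenario-contract violation: future region must differ only in climate",
         call. = FALSE)
  }
  presSurf <- lapply(models, predictGrid, region = present,
                     scenario = "present")
  futSurf <- lapply(models, predictGrid, region = future, scenario = scenario)
  delta <- lapply(stats::setNames(names(models), names(models)), function(s)
    surfaceValues(futSurf[[s]]) - surfaceValues(presSurf[[s]]))
  haveAll <- all(SEASONS %in% names(models))
  summary <- if (haveAll) {
    rbind(seasonalAnnual(presSurf[SEASONS], thresholds)$summary,
          seasonalAnnual(futSurf[SEASONS], thresholds)$summary)
  } else {
    do.call(rbind, c(lapply(presSurf, function(s)
      classifyLevels(s, thresholds)$summary),
      lapply(futSurf, function(s) classifyLevels(s, thresholds)$summary)))
  }
  list(present = presSurf, future = futSurf, delta = delta, summary = summary)
}
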