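# Configuration-driven orchestration of the five stages:
# simulate -> extract -> screen -> fit -> predict/scenario.

#' Pipeline configuration
#'
#' Bundles and validates every knob of the end-to-end run. Defaults mirror
#' the study conditions the package emulates: 125 sites, 30 m cells,
#' buffers 100-1000 m in 100 m steps, stepwise entry p <= 0.05 and removal
#' p > 0.10, 10-fold cross-validation, and 30/40 ppb level thresholds.
#'
#' @param region region parameters from [regionConfig()].
#' @param nSites number of monitoring sites.
#' @param urbanWeight urban placement weight for [placeSites()].
#' @param truth named list of [TruthModel-class] objects.
#' @param radii candidate buffer radii (m).
#' @param thresholdLow,thresholdHigh screening |r| thresholds.
#' @param pEnter,pRemove stepwise thresholds.
#' @param k cross-validation folds.
#' @param levelThresholds ppb classification thresholds.
#' @param scenarios named list of per-season climate deltas
#'   (see [defaultScenarioDeltas()]).
#' @param seed master seed; all stage seeds derive from it.
#' @param outDir optional directory for artifact files.
#' @return validated configuration list (class `lurConfig`).
#' @export
pipelineConfig <- function(region = regionConfig(), nSites = 125,
                           urbanWeight = 0.9, truth = defaultTruthModels(),
                           radii = seq(100, 1000, by = 100),
                           thresholdLow = 0.2, thresholdHigh = 0.7,
                           pEnter = 0.05, pRemove = 0.10, k = 10,
                           levelThresholds = c(30, 40),
                           scenarios = defaultScenarioDeltas(),
                           seed = 1, outDir = NULL) {
  stopIfNot(nSites >= 1, "nSites must be >= 1")
  stopIfNot(all(radii > 0), "radii must be positive")
  stopIfNot(pEnter < pRemove, "pEnter must be smaller than pRemove")
  stopIfNot(k >= 2, "k must be >= 2")
  stopIfNot(length(levelThresholds) == 2 &&
              levelThresholds[1] < levelThresholds[2],
            "levelThresholds must be an increasing pair")
  for (tm in truth) {
    stopIfNot(methods::is(tm, "TruthModel"), "truth must hold TruthModel objects")
  }
  structure(list(region = region, nSites = nSites, urbanWeight = urbanWeight,
                 truth = truth, radii = radii, thresholdLow = thresholdLow,
                 thresholdHigh = thresholdHigh, pEnter = pEnter,
                 pRemove = pRemove, k = k, levelThresholds = levelThresholds,
                 scenarios = scenarios, seed = seed, outDir = outDir),
            class = "lurConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Reads the scalar knobs of [pipelineConfig()] from a YAML file (region
#' sub-keys are passed to [regionConfig()]; truth models and scenarios keep
#' their in-code defaults unless given as nested lists mirroring their
#' constructors).
#'
#' @param path YAML file path.
#' @return configuration list from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$region)) args$region <- do.call(regionConfig, y$region)
  for (key in c("nSites", "urbanWeight", "thresholdLow", "thresholdHigh",
                "pEnter", "pRemove", "k", "seed", "outDir")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$radii)) args$radii <- as.numeric(y$radii)
  if (!is.null(y$levelThresholds)) {
    args$levelThresholds <- as.numeric(y$levelThresholds)
  }
  do.call(pipelineConfig, args)
}

#' Run the full pipeline
#'
#' Executes simulate, extract, screen, fit, predict and scenario stages in
#' order, entirely driven by the configuration: generates the synthetic
#' region and sites, simulates seasonal concentrations from the truth
#' models, builds the covariate cube, screens variables, fits the four
#' seasonal models, spatializes them on the grid, classifies levels, and
#' re-predicts under each climate scenario with land use held fixed.
#' Deterministic: rerunning with the same configuration reproduces every
#' artifact. When `config$outDir` is set the artifacts are also written as
#' text files (CSV/JSON/ASCII grid/GeoJSON).
#'
#' @param config list from [pipelineConfig()].
#' @param quiet suppress stage progress messages.
#' @return bundle list (class `lurPipeline`) with elements `config`,
#'   `region`, `sites`, `concentrations`, `cube`, `screening`, `models`,
#'   `surfaces` (present, incl. `annual`), `scenarios` (per scenario:
#'   `region`, `surfaces`, `delta`, `summary`), and `levels` (all level
#'   fractions).
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
  stopIfNot(inherits(config, "lurConfig"),
            "config must come from pipelineConfig()")
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                sprintf(fmt, ...)))
  }
  seeds <- list(region = subSeed(config$seed, 1), sites = subSeed(config$seed, 2),
                noise = subSeed(config$seed, 3), cv = subSeed(config$seed, 4))

  say("simulate: generating region and %d sites", config$nSites)
  region <- generateRegion(config$region, seed = seeds$region)
  sites <- placeSites(region, n = config$nSites,
                      urbanWeight = config$urbanWeight, seed = seeds$sites)
  conc <- simulateConcentrations(region, sites, config$truth,
                                 seed = seeds$noise)

  say("extract: building covariate cube over %d radii", length(config$radii))
  cube <- buildFeatureCube(region, sites,
                           specs = defaultVariableSpecs(radii = config$radii))

  say("screen: buffer optimization and correlation screens")
  screening <- screenVariables(cube, conc, config$thresholdLow,
                               config$thresholdHigh)

  say("fit: bidirectional stepwise per season, k = %d CV", config$k)
  models <- fitAllSeasons(cube, conc, screening, pEnter = config$pEnter,
                          pRemove = config$pRemove, k = config$k,
                          cvSeed = seeds$cv)
  screening <- markStepwise(screening, models)

  say("predict: 30 m grid surfaces and level classification")
  surfaces <- lapply(models, predictGrid, region = region,
                     scenario = "present")
  agg <- seasonalAnnual(surfaces, config$levelThresholds)
  surfaces$annual <- agg$annual
  levels <- cbind(agg$summary, scenarioLabel = "present")

  scen <- list()
  for (nm in names(config$scenarios)) {
    say("scenario: %s re-prediction with land use fixed", nm)
    fut <- rcpPerturbation(region, config$scenarios[[nm]])
    cmp <- scenarioCompare(models, region, fut, scenario = nm,
                           thresholds = config$levelThresholds)
    futAgg <- seasonalAnnual(cmp$future[SEASONS], config$levelThresholds)
    scen[[nm]] <- list(region = fut,
                       surfaces = c(cmp$future, list(annual = futAgg$annual)),
                       delta = cmp$delta, summary = futAgg$summary)
    levels <- rbind(levels, cbind(futAgg$summary, scenarioLabel = nm))
  }

  bundle <- structure(list(config = config, seeds = seeds, region = region,
                           sites = sites, concentrations = conc, cube = cube,
                           screening = screening, models = models,
                           surfaces = surfaces, scenarios = scen,
                           levels = levels),
                      class = "lurPipeline")
  if (!is.null(config$outDir)) {
    say("write: artifacts to %s", config$outDir)
    writeBundle(bundle, config$outDir)
  }
  bundle
}

#' @export
print.lurPipeline <- function(x, ...) {
  cat("LUR pipeline bundle\n")
  cat(sprintf("  region: %d x %d cells, %d sites\n", nrow(x$region@landuse),
              ncol(x$region@landuse), nrow(x$sites)))
  cat(sprintf("  models: %s\n", paste(names(x$models), collapse = ", ")))
  cat(sprintf("  scenarios: %s\n",
              paste(names(x$scenarios), collapse = ", ")))
  invisible(x)
}

#' Summarize a pipeline bundle
#'
#' Renders the run into report tables: the buffer/screening table, a
#' coefficient table (constant plus one row per variable, in ppm, with
#' adjusted R-squared and CV RMSE), and the level-fraction table per
#' season and scenario.
#'
#' @param bundle a bundle from [runPipeline()].
#' @return list (class `lurReport`) with `screening`, `coefficients`,
#'   `levels` data.frames.
#' @export
pipelineReport <- function(bundle) {
  need <- c("screening", "models", "levels")
  if (!all(need %in% names(bundle)) || !length(bundle$models)) {
    stop("report error: incomplete bundle", call. = FALSE)
  }
  st <- bundle$screening@status
  buf <- bundle$screening@buffers
  bufStr <- vapply(st$variable, function(v) {
    b <- buf[buf$variable == v & !is.na(buf$radius), ]
    if (!nrow(b)) return("-")
    if ("static" %in% b$season) sprintf("%g m", b$radius[1])
    else paste(sprintf("%s %g m", substr(b$season, 1, 2), b$radius),
               collapse = ", ")
  }, character(1))
  screening <- data.frame(variable = st$variable, buffer = bufStr,
                          correlationScreens = ifelse(
                            st$status %in% c("kept", "dropped_stepwise"),
                            "O", "-"),
                          stepwise = ifelse(st$status == "kept", "O", "-"),
                          status = st$status, stringsAsFactors = FALSE)

  vars <- unique(unlist(lapply(bundle$models, function(m) m@terms$variable)))
  coef <- data.frame(term = c("constant", vars), stringsAsFactors = FALSE)
  for (s in names(bundle$models)) {
    m <- bundle$models[[s]]
    col <- c(m@intercept, vapply(vars, function(v) {
      i <- match(v, m@terms$variable)
      if (is.na(i)) 0 else m@terms$coefficient[i]
    }, numeric(1)))
    coef[[s]] <- col
  }
  metrics <- data.frame(term = c("adjusted_R2", "cv_RMSE_ppb"),
                        stringsAsFactors = FALSE)
  for (s in names(bundle$models)) {
    metrics[[s]] <- c(bundle$models[[s]]@adjR2, bundle$models[[s]]@cvRMSE)
  }
  structure(list(screening = screening, coefficients = coef,
                 metrics = metrics, levels = bundle$levels),
            class = "lurReport")
}

#' @export
print.lurReport <- function(x, ...) {
  cat("== Buffer selection and screening ==\n")
  print(x$screening, row.names = FALSE)
  cat("\n== Seasonal model coefficients (ppm per unit) ==\n")
  print(x$coefficients, row.names = FALSE, digits = 3)
  print(x$metrics, row.names = FALSE, digits = 3)
  cat("\n== Concentration level fractions ==\n")
  print(x$levels, row.names = FALSE, digits = 3)
  invisible(x)
}
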