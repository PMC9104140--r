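#' Simulate seasonal site concentrations from a truth model
#'
#' Computes each truth term's covariate at every site with the site-level
#' extraction functions, forms the linear predictor
#' `1000 * (intercept + sum(coefficient * covariate))` in ppb, and adds
#' Gaussian noise of the model's `noiseSd`. Negative draws are clipped to 0
#' and counted (attribute `clipped`, also reported via a warning).
#'
#' @param region a [SyntheticRegion-class].
#' @param sites site data.frame from [placeSites()].
#' @param truth a [TruthModel-class] or a named list of them (one per
#'   season), e.g. [defaultTruthModels()].
#' @param seed integer seed for the noise draws.
#' @return data.frame `id`, `season`, `no2_ppb`, one row per (site, season),
#'   with attribute `clipped` (named count per season).
#' @examples
#' region <- generateRegion(regionConfig(width = 60, height = 60), seed = 1)
#' sites <- placeSites(region, n = 10, seed = 2)
#' conc <- simulateConcentrations(region, sites, defaultTruthModels(), seed = 3)
#' head(conc)
#' @export
simulateConcentrations <- function(region, sites, truth, seed = 1) {
  if (methods::is(truth, "TruthModel")) {
    truth <- stats::setNames(list(truth), truth@season)
  }
  specs <- defaultVariableSpecs()
  out <- vector("list", length(truth))
  clipped <- integer(0)
  withSeed(seed, {
    for (k in seq_along(truth)) {
      tm <- truth[[k]]
      stopIfNot(methods::is(tm, "TruthModel"), "truth must hold TruthModel objects")
      mu <- truthPredictor(region, sites, tm, specs)
      eps <- if (tm@noiseSd > 0) stats::rnorm(nrow(sites), 0, tm@noiseSd) else 0
      ppb <- mu + eps
      nClip <- sum(ppb < 0)
      if (nClip > 0) {
        warning(sprintf("%d simulated %s concentration(s) clipped to 0 ppb",
                        nClip, tm@season), call. = FALSE)
        ppb <- pmax(ppb, 0)
      }
      clipped[tm@season] <- nClip
      out[[k]] <- data.frame(id = sites$id, season = tm@season,
                             no2_ppb = ppb, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "clipped") <- clipped
  res
}

# Noiseless linear predictor (ppb) of a truth model at the sites, computed
# through the feature-extraction module (buildFeatureCube, i.e. the same
# buffer-extraction route the screening and fitting stages consume).
truthPredictor <- function(region, sites, tm, specs = defaultVariableSpecs()) {
  n <- nrow(sites)
  mu <- rep(tm@intercept, n)
  if (nrow(tm@terms)) {
    j <- match(tm@terms$variable, specs$name)
    if (anyNA(j)) {
      stop(sprintf("model specification error: unknown variable '%s'",
                   tm@terms$variable[which(is.na(j))[1]]), call. = FALSE)
    }
    sub <- specs[j, ]
    sub$radii <- lapply(seq_len(nrow(sub)), function(i)
      tm@terms$radius[i][!is.na(tm@terms$radius[i])])
    cube <- buildFeatureCube(region, sites, sub)
    for (i in seq_len(nrow(tm@terms))) {
      x <- featureValues(cube, tm@terms$variable[i],
                         radius = if (is.na(tm@terms$radius[i])) NULL else
                           tm@terms$radius[i],
                         season = if (sub$seasonal[i]) tm@season else NULL)
      mu <- mu + tm@terms$coefficient[i] * x
    }
  }
  1000 * mu
}
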