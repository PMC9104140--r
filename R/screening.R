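# Buffer-size optimization and the two correlation screens that produce the
# decisive variable set handed to stepwise regression.

#' Pearson correlation with the screening contracts
#'
#' Pearson product-moment correlation, with the preconditions the screening
#' pipeline relies on made explicit: equal length of at least 3 and non-zero
#' variance in both vectors (otherwise an undefined-correlation error).
#'
#' @param x,y numeric vectors.
#' @return correlation in `[-1, 1]`.
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearsonR <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(length(x) >= 3, "need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

# NA-returning variant used inside screening loops.
safePearson <- function(x, y) {
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Seasonal concentration vectors aligned to the cube's site order.
concBySeason <- function(conc, siteOrder) {
  out <- list()
  for (s in unique(conc$season)) {
    sub <- conc[conc$season == s, ]
    out[[s]] <- stats::setNames(sub$no2_ppb, sub$id)[siteOrder]
  }
  out
}

# Covariate vector for a variable at a given radius in a given season,
# falling back to the static slice for non-seasonal variables.
screenValues <- function(cube, variable, radius, season) {
  seasonal <- cube@specs$seasonal[match(variable, cube@specs$name)]
  kind <- cube@specs$kind[match(variable, cube@specs$name)]
  if (identical(kind, "distance")) {
    featureValues(cube, variable, NULL, NULL)
  } else if (isTRUE(seasonal)) {
    featureValues(cube, variable, radius, season)
  } else {
    featureValues(cube, variable, radius, NULL)
  }
}

#' Optimum buffer selection for one variable
#'
#' Scans the candidate radii and picks, per season for seasonal variables
#' and once (maximizing the mean over seasons of |r|) for static variables,
#' the radius whose extracted covariate is most correlated (in absolute
#' value) with the seasonal concentrations. Exact ties go to the smallest
#' radius. The distance-to-coast variable has no radii and reports `NA`.
#'
#' @param cube a [FeatureCube-class] holding the variable at >= 2 radii.
#' @param conc concentration data.frame (`id`, `season`, `no2_ppb`).
#' @param variable variable name.
#' @return list with `buffers` (data.frame `season`, `radius`, `r`; season
#'   `"static"` for non-seasonal variables) and `profile` (data.frame
#'   `season`, `radius`, `r` over all candidates).
#' @export
selectBuffer <- function(cube, conc, variable) {
  specs <- cube@specs
  j <- match(variable, specs$name)
  stopIfNot(!is.na(j), sprintf("unknown variable '%s'", variable))
  kind <- specs$kind[j]
  cs <- concBySeason(conc, cube@sites)
  seasons <- intersect(SEASONS, names(cs))
  stopIfNot(length(seasons) > 0, "no seasonal concentrations supplied")

  if (kind == "distance") {
    x <- featureValues(cube, variable, NULL, NULL)
    rr <- vapply(seasons, function(s) safePearson(x, cs[[s]]), numeric(1))
    buffers <- data.frame(season = "static", radius = NA_real_,
                          r = rr[which.max(abs(rr))],
                          stringsAsFactors = FALSE)
    profile <- data.frame(season = seasons, radius = NA_real_, r = rr,
                          stringsAsFactors = FALSE)
    return(list(buffers = buffers, profile = profile))
  }

  radii <- sort(specs$radii[[j]])
  stopIfNot(length(radii) >= 2,
            sprintf("'%s' needs at least two candidate radii", variable))

  if (specs$seasonal[j]) {
    profile <- do.call(rbind, lapply(seasons, function(s) {
      r <- vapply(radii, function(rad)
        safePearson(featureValues(cube, variable, rad, s), cs[[s]]),
        numeric(1))
      data.frame(season = s, radius = radii, r = r, stringsAsFactors = FALSE)
    }))
    buffers <- do.call(rbind, lapply(seasons, function(s) {
      p <- profile[profile$season == s, ]
      if (all(is.na(p$r))) {
        stop(sprintf("screening error: correlation undefined at every radius for '%s'",
                     variable), call. = FALSE)
      }
      best <- which(abs(p$r) == max(abs(p$r), na.rm = TRUE))[1]  # radii sorted: ties -> smallest
      data.frame(season = s, radius = p$radius[best], r = p$r[best],
                 stringsAsFactors = FALSE)
    }))
  } else {
    x <- lapply(radii, function(rad) featureValues(cube, variable, rad, NULL))
    profile <- do.call(rbind, lapply(seq_along(radii), function(i) {
      data.frame(season = seasons, radius = radii[i],
                 r = vapply(seasons, function(s)
                   safePearson(x[[i]], cs[[s]]), numeric(1)),
                 stringsAsFactors = FALSE)
    }))
    meanAbs <- vapply(radii, function(rad) {
      mean(abs(profile$r[profile$radius == rad]))
    }, numeric(1))
    if (all(is.na(meanAbs))) {
      stop(sprintf("screening error: correlation undefined at every radius for '%s'",
                   variable), call. = FALSE)
    }
    best <- which(meanAbs == max(meanAbs, na.rm = TRUE))[1]
    pr <- profile$r[profile$radius == radii[best]]
    buffers <- data.frame(season = "static", radius = radii[best],
                          r = pr[which.max(abs(pr))], stringsAsFactors = FALSE)
  }
  list(buffers = buffers, profile = profile)
}

# chosen radius for (variable, season) from a buffers table
chosenRadius <- function(buffers, variable, season) {
  b <- buffers[buffers$variable == variable, ]
  if (!nrow(b)) return(NA_real_)
  if ("static" %in% b$season) return(b$radius[b$season == "static"][1])
  b$radius[b$season == season][1]
}

# max-over-seasons |r| vs response at the chosen buffers
responseCorrelations <- function(cube, conc, buffers) {
  cs <- concBySeason(conc, cube@sites)
  seasons <- intersect(SEASONS, names(cs))
  vars <- unique(buffers$variable)
  out <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    rr <- vapply(seasons, function(s)
      abs(safePearson(screenValues(cube, v, chosenRadius(buffers, v, s), s),
                      cs[[s]])), numeric(1))
    out[v] <- if (all(is.na(rr))) NA_real_ else max(rr, na.rm = TRUE)
  }
  out
}

#' First screen: response correlation
#'
#' Keeps the variables whose maximum over seasons of |r| against the
#' seasonal concentrations (at the chosen buffers) reaches `thresholdLow`;
#' the rest are marked `dropped_low_response_corr`.
#'
#' @param cube a [FeatureCube-class].
#' @param conc concentration data.frame.
#' @param buffers buffer table with columns `variable`, `season`, `radius`
#'   (as assembled by [screenVariables()] from [selectBuffer()] calls).
#' @param thresholdLow |r| threshold (default 0.2).
#' @return list with `kept`, `dropped` (character vectors) and `rResponse`
#'   (named numeric).
#' @export
firstScreen <- function(cube, conc, buffers, thresholdLow = 0.2) {
  rResp <- responseCorrelations(cube, conc, buffers)
  kept <- names(rResp)[!is.na(rResp) & rResp >= thresholdLow]
  if (!length(kept)) {
    stop("screening error: no variable passes the response-correlation screen",
         call. = FALSE)
  }
  list(kept = kept, dropped = setdiff(names(rResp), kept), rResponse = rResp)
}

#' Second screen: pairwise collinearity
#'
#' Among the variables kept by the first screen, examines every pair whose
#' maximum over seasons of pairwise |r| exceeds `thresholdHigh`, in
#' descending order of that correlation, and drops the member with the
#' weaker response correlation (`dropped_collinear`). Pairs involving an
#' already-dropped variable are skipped. Survivors form the decisive set.
#'
#' @param cube a [FeatureCube-class].
#' @param conc concentration data.frame.
#' @param buffers buffer table (see [firstScreen()]).
#' @param kept character vector from the first screen.
#' @param rResponse named response correlations from the first screen.
#' @param thresholdHigh pairwise |r| threshold (default 0.7).
#' @return list with `decisive`, `dropped` (data.frame `variable`, `with`),
#'   and `maxPairR` (named numeric over `kept`).
#' @export
secondScreen <- function(cube, conc, buffers, kept, rResponse,
                         thresholdHigh = 0.7) {
  seasons <- intersect(SEASONS, unique(conc$season))
  vals <- lapply(stats::setNames(seasons, seasons), function(s) {
    sapply(kept, function(v)
      screenValues(cube, v, chosenRadius(buffers, v, s), s))
  })
  pairR <- matrix(0, length(kept), length(kept),
                  dimnames = list(kept, kept))
  for (s in seasons) {
    cc <- abs(suppressWarnings(stats::cor(vals[[s]])))
    cc[is.na(cc)] <- 0
    pairR <- pmax(pairR, cc)
  }
  diag(pairR) <- 0
  dropped <- character(0); with <- character(0)
  if (length(kept) >= 2) {
    pairs <- which(upper.tri(pairR) & pairR > thresholdHigh, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(pairR[pairs], decreasing = TRUE)
      pairs <- pairs[ord, , drop = FALSE]
      for (i in seq_len(nrow(pairs))) {
        a <- kept[pairs[i, 1]]; b <- kept[pairs[i, 2]]
        if (a %in% dropped || b %in% dropped) next
        # drop the member with the weaker response correlation;
        # exact tie -> drop the lexicographically later name
        loser <- if (rResponse[a] < rResponse[b]) a
                 else if (rResponse[b] < rResponse[a]) b
                 else max(a, b)
        dropped <- c(dropped, loser)
        with <- c(with, setdiff(c(a, b), loser))
      }
    }
  }
  list(decisive = setdiff(kept, dropped),
       dropped = data.frame(variable = dropped, with = with,
                            stringsAsFactors = FALSE),
       maxPairR = apply(pairR, 1, max))
}

#' Run buffer optimization and both correlation screens
#'
#' End-to-end screening: optimum-buffer selection for every catalogued
#' variable, the response-correlation screen, and the collinearity screen,
#' assembled into a [ScreeningReport-class]. The stepwise column of the
#' report is filled in later by [markStepwise()] once the seasonal models
#' are fitted.
#'
#' @param cube a [FeatureCube-class].
#' @param conc concentration data.frame (`id`, `season`, `no2_ppb`).
#' @param thresholdLow first-screen |r| threshold (default 0.2).
#' @param thresholdHigh second-screen pairwise |r| threshold (default 0.7).
#' @return a [ScreeningReport-class].
#' @export
screenVariables <- function(cube, conc, thresholdLow = 0.2,
                            thresholdHigh = 0.7) {
  vars <- cube@specs$name
  sel <- lapply(stats::setNames(vars, vars), function(v)
    selectBuffer(cube, conc, v))
  buffers <- do.call(rbind, lapply(vars, function(v)
    cbind(variable = v, sel[[v]]$buffers, stringsAsFactors = FALSE)))
  profiles <- lapply(sel, `[[`, "profile")

  fs <- firstScreen(cube, conc, buffers, thresholdLow)
  ss <- secondScreen(cube, conc, buffers, fs$kept, fs$rResponse, thresholdHigh)

  status <- data.frame(variable = vars,
                       status = "kept", with = NA_character_,
                       rResponse = unname(fs$rResponse[vars]),
                       maxPairR = NA_real_, stringsAsFactors = FALSE)
  status$status[status$variable %in% fs$dropped] <- "dropped_low_response_corr"
  m <- match(ss$dropped$variable, status$variable)
  status$status[m] <- "dropped_collinear"
  status$with[m] <- ss$dropped$with
  status$maxPairR[match(names(ss$maxPairR), status$variable)] <- ss$maxPairR

  methods::new("ScreeningReport", buffers = buffers, status = status,
               profiles = profiles,
               thresholds = c(low = thresholdLow, high = thresholdHigh))
}

#' Decisive variables of a screening report
#'
#' @param report a [ScreeningReport-class].
#' @return character vector of variables surviving both screens.
#' @export
decisiveVariables <- function(report) {
  report@status$variable[report@status$status %in% c("kept", "dropped_stepwise")]
}

#' Record stepwise outcomes in a screening report
#'
#' Marks decisive variables that entered none of the fitted seasonal models
#' as `dropped_stepwise`.
#'
#' @param report a [ScreeningReport-class].
#' @param models list of [LURModel-class] objects.
#' @return updated [ScreeningReport-class].
#' @export
markStepwise <- function(report, models) {
  used <- unique(unlist(lapply(models, function(m) m@terms$variable)))
  st <- report@status
  idx <- st$status == "kept" & !(st$variable %in% used)
  st$status[idx] <- "dropped_stepwise"
  methods::initialize(report, status = st)
}
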