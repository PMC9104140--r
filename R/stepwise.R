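# Bidirectional p-value stepwise OLS with k-fold cross-validation: the
# model-development stage of the LUR pipeline. Entry requires the smallest
# candidate p-value <= pEnter (computed by full refit of the current model
# plus the candidate); removal evicts included terms with p > pRemove,
# largest first, refitting after each eviction.

#' Ordinary least squares with t-test p-values
#'
#' QR-based OLS of `y` on the columns of `x` (an intercept column is
#' prepended unless `intercept = FALSE`), returning coefficient estimates,
#' classical homoscedastic standard errors, two-sided t-test p-values and
#' R-squared. A constant response yields R-squared 0 with a warning; a
#' rank-deficient design is an error.
#'
#' @param x numeric matrix of covariates (may have zero columns).
#' @param y numeric response.
#' @param intercept prepend an intercept column (default `TRUE`).
#' @return list with `coefficients`, `se`, `t`, `p` (all named), `r2`,
#'   `sigma`, `residuals`, `fitted`, `df` (residual degrees of freedom).
#' @examples
#' fit <- olsFit(cbind(x = 0:2), c(1, 3, 5))
#' fit$coefficients
#' @export
olsFit <- function(x, y, intercept = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x)) colnames(x) <- paste0("x", seq_len(ncol(x)))
  X <- if (intercept) cbind(`(Intercept)` = 1, x) else x
  n <- length(y)
  stopIfNot(nrow(X) == n, "nrow(x) must match length(y)")
  stopIfNot(n > ncol(X), "need more observations than coefficients")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("singular design: columns are linearly dependent", call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- n - ncol(X)
  rss <- sum(res^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(0, diag(XtXinv) * sigma2))
  tval <- ifelse(se > 0, beta / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else {
    warning("constant response: R-squared undefined, reported as 0",
            call. = FALSE)
    0
  }
  list(coefficients = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)),
       t = stats::setNames(tval, colnames(X)),
       p = stats::setNames(pval, colnames(X)),
       r2 = r2, sigma = sqrt(sigma2), residuals = res, fitted = fitted,
       df = df)
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` for `p` predictors and `n`
#' observations; requires `n > p + 1`.
#'
#' @param r2 R-squared.
#' @param n number of observations.
#' @param p number of predictors (excluding the intercept).
#' @return adjusted R-squared.
#' @examples
#' adjustedR2(0.6, 125, 5)
#' @export
adjustedR2 <- function(r2, n, p) {
  stopIfNot(n > p + 1, "adjusted R-squared undefined: n must exceed p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Bidirectional p-value stepwise selection
#'
#' Alternates forward entry and backward elimination on the candidate
#' columns of `x`: each cycle adds the excluded candidate with the smallest
#' full-refit p-value when that p-value is at most `pEnter` (ties broken by
#' larger |r| with the response, then variable name), then repeatedly
#' removes the included term with the largest p-value above `pRemove`,
#' refitting after each removal. The loop ends when neither action fires. A
#' revisited model set (or exceeding `maxIter` cycles) triggers the cycle
#' guard: the visited model with the best adjusted R-squared is returned
#' with a warning.
#'
#' @param x numeric matrix of candidate covariates (named columns).
#' @param y numeric response.
#' @param pEnter entry threshold (default 0.05); must be < `pRemove`.
#' @param pRemove removal threshold (default 0.10).
#' @param maxIter cycle cap; defaults to `max(4, ncol(x)^2)`.
#' @return list with `included` (character), `fit` (the [olsFit()] of the
#'   final model), and `trace` (data.frame `iteration`, `action`,
#'   `variable`, `p`).
#' @export
bidirectionalStepwise <- function(x, y, pEnter = 0.05, pRemove = 0.10,
                                  maxIter = NULL) {
  x <- as.matrix(x)
  stopIfNot(ncol(x) >= 1, "need at least one candidate")
  stopIfNot(pEnter < pRemove, "pEnter must be smaller than pRemove")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  cand <- colnames(x)
  if (is.null(maxIter)) maxIter <- max(4L, length(cand)^2)
  marginalAbsR <- vapply(cand, function(v) abs(safePearson(x[, v], y)),
                         numeric(1))
  marginalAbsR[is.na(marginalAbsR)] <- 0

  included <- character(0)
  trace <- list()
  visited <- character(0)
  fits <- list()
  setKey <- function(s) paste(sort(s), collapse = "|")
  fitSet <- function(s) olsFit(x[, s, drop = FALSE], y)

  cycle <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    acted <- FALSE
    key <- setKey(included)
    if (key %in% visited || iter > maxIter) { cycle <- TRUE; break }
    visited <- c(visited, key)
    fits[[key]] <- fitSet(included)

    # forward entry
    excluded <- setdiff(cand, included)
    if (length(excluded)) {
      entryP <- vapply(excluded, function(v)
        fitSet(c(included, v))$p[[v]], numeric(1))
      best <- min(entryP, na.rm = TRUE)
      if (!is.na(best) && best <= pEnter) {
        ties <- excluded[!is.na(entryP) & entryP == best]
        if (length(ties) > 1) {
          ties <- ties[order(-marginalAbsR[ties], ties)]
        }
        vin <- ties[1]
        included <- c(included, vin)
        trace[[length(trace) + 1L]] <- data.frame(
          iteration = iter, action = "enter", variable = vin, p = best,
          stringsAsFactors = FALSE)
        acted <- TRUE
      }
    }

    # backward removal, largest offender first, refit after each
    repeat {
      if (!length(included)) break
      fit <- fitSet(included)
      pterm <- fit$p[included]
      worst <- which.max(pterm)
      if (pterm[worst] > pRemove) {
        vout <- included[worst]
        included <- setdiff(included, vout)
        trace[[length(trace) + 1L]] <- data.frame(
          iteration = iter, action = "remove", variable = vout,
          p = unname(pterm[worst]), stringsAsFactors = FALSE)
        acted <- TRUE
      } else break
    }

    if (!acted) break
  }

  if (cycle) {
    warning("stepwise cycle detected: returning the best visited model",
            call. = FALSE)
    adj <- vapply(names(fits), function(k) {
      f <- fits[[k]]
      p <- length(f$coefficients) - 1L
      adjustedR2(f$r2, length(y), p)
    }, numeric(1))
    included <- strsplit(names(which.max(adj)), "|", fixed = TRUE)[[1]]
    included <- included[nzchar(included)]
  }

  list(included = included, fit = fitSet(included),
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(iteration = integer(0), action = character(0),
                    variable = character(0), p = numeric(0)))
}

#' Pooled k-fold cross-validation RMSE
#'
#' Shuffles the observations with `seed`, splits them into `k` near-equal
#' folds, refits the coefficients of the fixed term set on each complement,
#' predicts the held-out fold, pools all out-of-fold residuals and returns
#' the root mean square (same units as `y`).
#'
#' @param x covariate matrix of the selected terms (zero columns allowed for
#'   an intercept-only model).
#' @param y response.
#' @param k number of folds (2 <= k <= n; `k = n` is leave-one-out).
#' @param seed shuffle seed.
#' @return RMSE.
#' @export
kfoldRMSE <- function(x, y, k = 10, seed = 1) {
  x <- as.matrix(x)
  n <- length(y)
  stopIfNot(k >= 2 && k <= n, "need n >= k >= 2")
  perm <- withSeed(seed, sample.int(n))
  foldOf <- integer(n)
  foldOf[perm] <- rep_len(seq_len(k), n)
  pooled <- numeric(n)
  for (f in seq_len(k)) {
    test <- foldOf == f
    nTrain <- sum(!test)
    if (nTrain <= ncol(x) + 1L) {
      stop("fold-size error: training folds smaller than the parameter count",
           call. = FALSE)
    }
    Xtr <- cbind(1, x[!test, , drop = FALSE])
    beta <- qr.coef(qr(Xtr), y[!test])
    beta[is.na(beta)] <- 0
    pred <- drop(cbind(1, x[test, , drop = FALSE]) %*% beta)
    pooled[test] <- y[test] - pred
  }
  sqrt(mean(pooled^2))
}

#' Fit one seasonal LUR model
#'
#' Assembles the candidate design from the decisive variables of a
#' screening report (each at its chosen buffer for the season), runs
#' [bidirectionalStepwise()] on the seasonal concentrations, and validates
#' the final model by [kfoldRMSE()]. Concentrations are regressed in ppb;
#' the returned model stores intercept and coefficients in ppm (divide by
#' 1000), with the CV RMSE in ppb. The selected term set is independent of
#' the CV seed; only `cvRMSE` depends on it.
#'
#' @param cube a [FeatureCube-class].
#' @param conc concentration data.frame.
#' @param report a [ScreeningReport-class].
#' @param season season to fit.
#' @param pEnter,pRemove stepwise thresholds (defaults 0.05 / 0.10).
#' @param k folds (default 10).
#' @param cvSeed shuffle seed for cross-validation.
#' @return a [LURModel-class].
#' @export
fitSeasonalLUR <- function(cube, conc, report, season, pEnter = 0.05,
                           pRemove = 0.10, k = 10, cvSeed = 1) {
  stopIfNot(season %in% SEASONS, sprintf("unknown season '%s'", season))
  cand <- decisiveVariables(report)
  stopIfNot(length(cand) > 0, "no decisive variables to fit")
  y <- concBySeason(conc, cube@sites)[[season]]
  stopIfNot(!is.null(y), sprintf("no concentrations for season '%s'", season))
  radii <- vapply(cand, function(v)
    chosenRadius(report@buffers, v, season), numeric(1))
  X <- sapply(cand, function(v)
    screenValues(cube, v, radii[[v]], season))
  step <- bidirectionalStepwise(X, y, pEnter = pEnter, pRemove = pRemove)
  fin <- step$included
  fit <- step$fit
  cv <- kfoldRMSE(X[, fin, drop = FALSE], y, k = k, seed = cvSeed)
  terms <- if (length(fin)) {
    data.frame(variable = fin, radius = unname(radii[fin]),
               coefficient = unname(fit$coefficients[fin]) / 1000,
               se = unname(fit$se[fin]) / 1000,
               p = unname(fit$p[fin]), stringsAsFactors = FALSE)
  } else {
    data.frame(variable = character(0), radius = numeric(0),
               coefficient = numeric(0), se = numeric(0), p = numeric(0))
  }
  methods::new("LURModel", season = season,
               intercept = unname(fit$coefficients[["(Intercept)"]]) / 1000,
               terms = terms, nSites = length(y),
               adjR2 = adjustedR2(fit$r2, length(y), length(fin)),
               cvRMSE = cv,
               criteria = list(pEnter = pEnter, pRemove = pRemove, k = k,
                               cvSeed = cvSeed),
               trace = step$trace)
}

#' Fit all four seasonal models
#'
#' @inheritParams fitSeasonalLUR
#' @return named list of [LURModel-class] objects (spring, summer, fall,
#'   winter, as present in `conc`).
#' @export
fitAllSeasons <- function(cube, conc, report, pEnter = 0.05, pRemove = 0.10,
                          k = 10, cvSeed = 1) {
  seasons <- intersect(SEASONS, unique(conc$season))
  stats::setNames(lapply(seasons, function(s)
    fitSeasonalLUR(cube, conc, report, s, pEnter, pRemove, k, cvSeed)),
    seasons)
}
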