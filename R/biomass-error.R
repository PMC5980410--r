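# ---- allometry fitting ------------------------------------------------------

#' Fit the zero-intercept height-to-DBH model from field pairs
#'
#' Least squares through the origin, `DBH = a * height` (DBH in cm, height
#' in m), with the standard-error of the slope, the residual RMSE and the
#' percent RMSE (residual RMSE over the mean DBH).
#'
#' @param field data.frame with columns `height_m` and `dbh_cm` (positive).
#' @param model optional [AllometricModel-class] whose Jenkins coefficients
#'   to carry over; defaults to the standard true fir/hemlock coefficients.
#' @return An [AllometricModel-class] with `a`, `sigmaA` and `rmseDbh`
#'   replaced by the fit (with a single pair, `sigmaA` and `rmseDbh` are
#'   `NA` and flagged with a warning). The %RMSE is attached as
#'   `attr(, "pctRmse")`.
#' @examples
#' fld <- data.frame(height_m = c(10, 20, 30), dbh_cm = c(22, 44, 66))
#' fitDbhModel(fld)  # slope exactly 2.2, RMSE 0
#' @export
fitDbhModel <- function(field, model = allometricModel()) {
  need <- c("height_m", "dbh_cm")
  if (!all(need %in% names(field))) {
    stop("field table must have columns height_m, dbh_cm", call. = FALSE)
  }
  h <- field$height_m; d <- field$dbh_cm
  if (any(!is.finite(h)) || any(!is.finite(d)) || any(h <= 0) || any(d <= 0)) {
    stop("heights and DBH values must be positive and finite", call. = FALSE)
  }
  if (sum(h^2) == 0) stop("degenerate fit: all heights zero", call. = FALSE)
  n <- length(h)
  a <- sum(h * d) / sum(h^2)
  resid <- d - a * h
  if (n >= 3L) {
    s2 <- sum(resid^2) / (n - 1L)
    sigmaA <- sqrt(s2 / sum(h^2))
    rmse <- sqrt(s2)
  } else {
    warning("fewer than 3 pairs: slope uncertainty and RMSE are undefined")
    sigmaA <- NA_real_
    rmse <- NA_real_
  }
  out <- allometricModel(a = a, sigmaA = sigmaA, rmseDbh = rmse,
                         jenkinsB0 = model@jenkinsB0,
                         jenkinsB1 = model@jenkinsB1,
                         sigmaLog = model@sigmaLog)
  attr(out, "pctRmse") <- if (is.na(rmse)) NA_real_ else 100 * rmse / mean(d)
  out
}

#' Predict stem diameter from tree height
#'
#' @param height tree height(s), metres (> 0).
#' @param model an [AllometricModel-class].
#' @return DBH in cm.
#' @examples
#' predictDbh(30, allometricModel())  # 66 cm
#' @export
predictDbh <- function(height, model = allometricModel()) {
  if (any(height <= 0)) stop("height must be positive", call. = FALSE)
  model@a * height
}

#' Jenkins generalized biomass equation (true fir/hemlock group)
#'
#' `biomass = exp(b0 + b1 * ln(DBH))`, kg per tree, DBH in cm.
#'
#' @param dbh stem diameter(s) at breast height, cm (> 0).
#' @param model an [AllometricModel-class] carrying `b0`, `b1`.
#' @return Biomass in kg.
#' @examples
#' jenkinsBiomass(50)  # ~1.298e3 kg
#' @export
jenkinsBiomass <- function(dbh, model = allometricModel()) {
  if (any(dbh <= 0)) stop("dbh must be positive", call. = FALSE)
  exp(model@jenkinsB0 + model@jenkinsB1 * log(dbh))
}

# ---- error components -------------------------------------------------------

#' Estimate the height measurement error from tall matched crowns
#'
#' The tallest, most mature trees are assumed to grow negligibly over the
#' interval, so any apparent height change among matched crowns above
#' `heightFloor` measures the height error of the extraction chain. The
#' default estimator is the mean absolute difference; the SD of differences
#' is available as an alternative. The error is treated as constant in
#' absolute terms across size classes, because apex detection does not get
#' easier for shorter trees.
#'
#' @param matches match table with `height_1`, `height_2`.
#' @param heightFloor only pairs with both heights above this are used,
#'   metres.
#' @param estimator `"meanabs"` (mean absolute difference) or `"sd"` (SD of
#'   differences).
#' @param minPairs minimum usable pairs.
#' @return `sigma_ht` in metres, with the pair count as `attr(, "nPairs")`.
#' @export
heightMeasurementError <- function(matches, heightFloor = 50,
                                   estimator = c("meanabs", "sd"),
                                   minPairs = 10L) {
  estimator <- match.arg(estimator)
  tall <- matches$height_1 > heightFloor & matches$height_2 > heightFloor
  d <- matches$height_2[tall] - matches$height_1[tall]
  d <- d[is.finite(d)]
  if (length(d) < minPairs) {
    stop("only ", length(d), " matched pairs above ", heightFloor,
         " m (need ", minPairs, ")", call. = FALSE)
  }
  out <- if (estimator == "meanabs") mean(abs(d)) else sd(d)
  attr(out, "nPairs") <- length(d)
  out
}

#' Combine fractional DBH error components by root sum of squares
#'
#' `frac_dbh = sqrt(frac_ht^2 + frac_param^2 + frac_resid^2)`: the height
#' measurement error, the slope parameter error and the residual spread of
#' the DBH model, each expressed as a fraction, combined in quadrature.
#'
#' @param fracHt fractional height error(s) (`sigma_ht / height`).
#' @param fracParam fractional slope error (`sigma_a / a`).
#' @param fracResid fractional residual DBH error (`rmse / DBH`).
#' @return Fractional DBH error.
#' @examples
#' dbhFractionalError(0.077, 0.063, 0.217)  # ~0.239, i.e. 24%
#' @export
dbhFractionalError <- function(fracHt, fracParam, fracResid) {
  if (any(c(fracHt, fracParam, fracResid) < 0, na.rm = TRUE)) {
    stop("fractional errors must be nonnegative", call. = FALSE)
  }
  sqrt(fracHt^2 + fracParam^2 + fracResid^2)
}

#' Per-tree biomass error from DBH error and allometric scatter
#'
#' The DBH error is amplified through the biomass equation's exponent,
#' `sigma_m_dbh = M * b1 * frac_dbh`; the allometric residual scatter in log
#' space becomes the lognormal SD
#' `sigma_allom = sqrt(exp(2*s^2 + 2*mu) - exp(s^2 + 2*mu))` with
#' `mu = ln(M)` and `s` the log-space error — equivalently
#' `M * exp(s^2/2) * sqrt(exp(s^2) - 1)`; the two combine in quadrature to
#' the per-tree biomass error `sigma_agb`.
#'
#' @param M estimated biomass, kg (> 0), vectorised.
#' @param fracDbh fractional DBH error per tree.
#' @param model an [AllometricModel-class].
#' @return data.frame: `sigmaMDbh`, `sigmaAllom`, `sigmaAgb` (kg).
#' @export
biomassErrorPerTree <- function(M, fracDbh, model = allometricModel()) {
  stopifnot(all(M > 0), all(fracDbh >= 0))
  s <- model@sigmaLog
  sigmaMDbh <- M * model@jenkinsB1 * fracDbh
  sigmaAllom <- M * exp(s^2 / 2) * sqrt(exp(s^2) - 1)
  data.frame(sigmaMDbh = sigmaMDbh, sigmaAllom = sigmaAllom,
             sigmaAgb = sqrt(sigmaMDbh^2 + sigmaAllom^2))
}

#' Fractional allometric-fit error implied by the log-space residual
#'
#' The lognormal coefficient of variation, `sqrt(exp(s^2) - 1)`, for the
#' biomass equation's log-space standard error `s`.
#'
#' @param model an [AllometricModel-class] (or a bare sigma value).
#' @return Dimensionless CV.
#' @examples
#' allometricFitCV(allometricModel())  # ~0.184
#' @export
allometricFitCV <- function(model = allometricModel()) {
  s <- if (is(model, "AllometricModel")) model@sigmaLog else as.numeric(model)
  sqrt(exp(s^2) - 1)
}

# ---- full budget ------------------------------------------------------------

#' Build the full per-tree error budget for one epoch
#'
#' Runs the whole chain for a vector of tree heights: DBH prediction,
#' per-tree fractional errors (constant absolute height error over height;
#' slope error; residual RMSE over predicted DBH), fractional RSS to DBH
#' error, amplification through the biomass exponent, quadrature with the
#' allometric scatter, and aggregation to the epoch total. The total's
#' error is the linear sum of per-tree errors by default — per-tree errors
#' are dominated by shared model terms and are treated as fully correlated —
#' with independent (RSS) aggregation available.
#'
#' @param heights tree heights, metres.
#' @param model an [AllometricModel-class] (fitted; needs `sigmaA`,
#'   `rmseDbh`).
#' @param sigmaHt height measurement error, metres
#'   ([heightMeasurementError()]).
#' @param totalMethod `"linear"` (fully correlated) or `"rss"` (independent).
#' @return An [ErrorBudget-class].
#' @export
errorBudget <- function(heights, model, sigmaHt,
                        totalMethod = c("linear", "rss")) {
  totalMethod <- match.arg(totalMethod)
  stopifnot(all(heights > 0), sigmaHt >= 0)
  if (!is.finite(model@sigmaA) || !is.finite(model@rmseDbh)) {
    stop("model must carry sigmaA and rmseDbh (fit it with fitDbhModel)",
         call. = FALSE)
  }
  dbh <- predictDbh(heights, model)
  M <- jenkinsBiomass(dbh, model)
  fracHt <- sigmaHt / heights
  fracParam <- rep(model@sigmaA / model@a, length(heights))
  fracResid <- model@rmseDbh / dbh
  fracDbh <- dbhFractionalError(fracHt, fracParam, fracResid)
  err <- biomassErrorPerTree(M, fracDbh, model)
  perTree <- data.frame(height = heights, dbh = dbh, biomass = M,
                        fracHt = fracHt, fracParam = fracParam,
                        fracResid = fracResid, fracDbh = fracDbh, err)
  sigmaTotal <- if (totalMethod == "linear") sum(err$sigmaAgb) else
    sqrt(sum(err$sigmaAgb^2))
  new("ErrorBudget", perTree = perTree, sigmaHt = as.numeric(sigmaHt),
      total = sum(M), sigmaTotal = sigmaTotal)
}

#' Aggregate epoch totals and the biomass change with its error
#'
#' Totals are plain sums. The change is `total_2 - total_1`; its error
#' combines the two epochs' fractional total errors in quadrature by
#' default (`|change| * sqrt(f_1^2 + f_2^2)` with `f = sigma_total/total`),
#' with a linear-sum alternative (`|change| * (f_1 + f_2)`).
#'
#' @param biomass1,biomass2 per-tree biomass vectors, kg (or epoch totals of
#'   length 1).
#' @param sigma1,sigma2 matching per-tree error vectors, kg.
#' @param totalMethod `"linear"` or `"rss"` aggregation of per-tree errors.
#' @param changeMethod `"quadrature"` or `"linear"` combination of the two
#'   epochs' fractional errors.
#' @return list: `total_1`, `total_2`, `sigmaTotal_1`, `sigmaTotal_2`,
#'   `frac_1`, `frac_2`, `agbChange`, `sigmaChange`.
#' @examples
#' aggregateTotals(359.67, 208.53, 285.09, 172.73)  # change -74.58 +/- 62.54
#' @export
aggregateTotals <- function(biomass1, sigma1, biomass2, sigma2,
                            totalMethod = c("linear", "rss"),
                            changeMethod = c("quadrature", "linear")) {
  totalMethod <- match.arg(totalMethod)
  changeMethod <- match.arg(changeMethod)
  if (!length(biomass1) || !length(biomass2)) {
    stop("both epochs must be nonempty", call. = FALSE)
  }
  t1 <- sum(biomass1); t2 <- sum(biomass2)
  s1 <- if (totalMethod == "linear") sum(sigma1) else sqrt(sum(sigma1^2))
  s2 <- if (totalMethod == "linear") sum(sigma2) else sqrt(sum(sigma2^2))
  f1 <- s1 / t1; f2 <- s2 / t2
  change <- t2 - t1
  sigmaChange <- if (changeMethod == "quadrature") {
    abs(change) * sqrt(f1^2 + f2^2)
  } else {
    abs(change) * (f1 + f2)
  }
  list(total_1 = t1, total_2 = t2, sigmaTotal_1 = s1, sigmaTotal_2 = s2,
       frac_1 = f1, frac_2 = f2, agbChange = change,
       sigmaChange = sigmaChange)
}

# ---- Monte-Carlo oracle -----------------------------------------------------

#' Monte-Carlo validation of the analytic error chain
#'
#' Draws the error sources directly — height error `N(0, sigmaHt)` per tree,
#' slope error `N(a, sigmaA)` shared across trees within a draw (parameter
#' error is common to every tree), residual DBH error `N(0, rmseDbh)` per
#' tree, and multiplicative lognormal allometric scatter `exp(N(0,
#' sigmaLog))` per tree — and reports the empirical SD of the per-tree DBH,
#' the per-tree biomass, and the site total, for comparison with the
#' analytic chain. Any subset of sources can be switched on.
#'
#' @param heights tree heights, metres.
#' @param model a fitted [AllometricModel-class].
#' @param sigmaHt height measurement error, metres.
#' @param nDraws number of draws (>= 1e4 recommended).
#' @param seed integer seed.
#' @param sources character subset of
#'   `c("height", "param", "resid", "allom")`.
#' @return list: `dbhSd`, `biomassSd`, `biomassMean` (per-tree vectors),
#'   `totalSd`, `totalMean`.
#' @export
monteCarloErrorOracle <- function(heights, model, sigmaHt, nDraws = 1e5,
                                  seed = 1L,
                                  sources = c("height", "param", "resid",
                                              "allom")) {
  sources <- match.arg(sources, several.ok = TRUE)
  nT <- length(heights)
  withr::with_seed(as.integer(seed), {
    h <- matrix(heights, nrow = nDraws, ncol = nT, byrow = TRUE)
    if ("height" %in% sources && sigmaHt > 0) {
      h <- h + matrix(rnorm(nDraws * nT, 0, sigmaHt), nDraws, nT)
      h <- pmax(h, 0.1)
    }
    a <- if ("param" %in% sources && is.finite(model@sigmaA)) {
      rnorm(nDraws, model@a, model@sigmaA)
    } else rep(model@a, nDraws)
    dbh <- h * a
    if ("resid" %in% sources && is.finite(model@rmseDbh)) {
      dbh <- dbh + matrix(rnorm(nDraws * nT, 0, model@rmseDbh), nDraws, nT)
    }
    dbh <- pmax(dbh, 0.1)
    M <- exp(model@jenkinsB0 + model@jenkinsB1 * log(dbh))
    if ("allom" %in% sources && model@sigmaLog > 0) {
      M <- M * exp(matrix(rnorm(nDraws * nT, 0, model@sigmaLog), nDraws, nT))
    }
    tot <- rowSums(M)
    list(dbhSd = apply(dbh, 2, sd), biomassSd = apply(M, 2, sd),
         biomassMean = colMeans(M), totalSd = sd(tot), totalMean = mean(tot))
  })
}

# ---- change by class --------------------------------------------------------

#' Biomass change by first-epoch height class
#'
#' Per height class: biomass gained by matched survivors (the Jenkins
#' biomass at the second-epoch height minus at the first-epoch height),
#' biomass lost through detected loss events (the lost crowns' first-epoch
#' biomass), and the net change.
#'
#' @param matches filtered match table (`height_1`, `height_2`).
#' @param events loss-event table (`height_1`).
#' @param model an [AllometricModel-class].
#' @param binWidth class width, metres.
#' @return data.frame: `binLower`, `binUpper`, `nMatched`, `nLost`, `gain`,
#'   `loss`, `net` (kg).
#' @export
biomassChangeByClass <- function(matches, events, model = allometricModel(),
                                 binWidth = 5) {
  gBin <- floor(matches$height_1 / binWidth)
  gain <- jenkinsBiomass(predictDbh(pmax(matches$height_2, 0.1), model), model) -
    jenkinsBiomass(predictDbh(matches$height_1, model), model)
  lBin <- if (nrow(events)) floor(events$height_1 / binWidth) else integer(0)
  loss <- if (nrow(events)) {
    jenkinsBiomass(predictDbh(events$height_1, model), model)
  } else numeric(0)
  bins <- sort(unique(c(gBin, lBin)))
  out <- lapply(bins, function(b) {
    data.frame(binLower = b * binWidth, binUpper = (b + 1) * binWidth,
               nMatched = sum(gBin == b), nLost = sum(lBin == b),
               gain = sum(gain[gBin == b]), loss = sum(loss[lBin == b]),
               net = sum(gain[gBin == b]) - sum(loss[lBin == b]))
  })
  do.call(rbind, out)
}
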