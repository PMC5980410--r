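test_that("the zero-intercept DBH model fits exactly and under noise", {
  exact <- data.frame(height_m = c(10, 20, 30, 40), dbh_cm = 2.2 * c(10, 20, 30, 40))
  m <- fitDbhModel(exact)
  expect_equal(m@a, 2.2, tolerance = 1e-12)
  expect_lt(m@rmseDbh, 1e-9)

  set.seed(21)
  h <- runif(200, 20, 60)
  noisy <- data.frame(height_m = h,
                      dbh_cm = pmax(0.5, 2.2 * h + rnorm(200, 0, 15.5)))
  mn <- fitDbhModel(noisy)
  expect_lt(abs(mn@a - 2.2), 2 * mn@sigmaA)
  expect_lt(abs(mn@rmseDbh - 15.5) / 15.5, 0.15)
  expect_true(is.finite(attr(mn, "pctRmse")))

  expect_warning(single <- fitDbhModel(data.frame(height_m = 10, dbh_cm = 22)),
                 "undefined")
  expect_equal(single@a, 2.2)
  expect_true(is.na(single@sigmaA))
})

test_that("DBH prediction and the biomass equation match closed forms", {
  m <- allometricModel()
  expect_equal(predictDbh(30, m), 66)
  # independent high-precision evaluation of the biomass equation
  expect_equal(jenkinsBiomass(50, m), exp(-2.5384 + 2.4814 * log(50)),
               tolerance = 1e-12)
  expect_lt(abs(jenkinsBiomass(50, m) - 1.298e3) / 1.298e3, 1e-3)
  expect_equal(jenkinsBiomass(1, m), exp(-2.5384), tolerance = 1e-12)
  expect_error(predictDbh(-1, m), "positive")
  expect_error(jenkinsBiomass(0, m), "positive")

  # scale equivariance: heights x c -> biomass x c^b1
  h <- c(10, 25, 40)
  b <- jenkinsBiomass(predictDbh(h, m), m)
  b3 <- jenkinsBiomass(predictDbh(3 * h, m), m)
  expect_equal(b3 / b, rep(3^2.4814, 3), tolerance = 1e-12)
})

test_that("height measurement error estimators match their expectations", {
  same <- data.frame(height_1 = runif(40, 51, 70))
  same$height_2 <- same$height_1
  expect_equal(as.numeric(heightMeasurementError(same)), 0)

  set.seed(22)
  tall <- data.frame(height_1 = runif(500, 55, 70))
  tall$height_2 <- tall$height_1 + rnorm(500, 0, 1)
  # half-normal expectation: mean |N(0,1)| = sqrt(2/pi) ~ 0.798
  ma <- heightMeasurementError(tall)
  expect_lt(abs(ma - sqrt(2 / pi)), 0.08)
  sdv <- heightMeasurementError(tall, estimator = "sd")
  expect_lt(abs(sdv - 1), 0.12)

  few <- tall[1:5, ]
  expect_error(heightMeasurementError(few), "need 10")
})

test_that("fractional DBH error is a root sum of squares", {
  v <- dbhFractionalError(0.077, 0.063, 0.217)
  expect_equal(v, sqrt(0.077^2 + 0.063^2 + 0.217^2), tolerance = 1e-12)
  expect_equal(round(100 * v), 24)
  expect_equal(dbhFractionalError(0, 0, 0), 0)
  expect_equal(dbhFractionalError(0.3, 0, 0), 0.3)
  expect_error(dbhFractionalError(-0.1, 0, 0), "nonnegative")
})

test_that("per-tree biomass errors follow the propagation formulas", {
  m <- allometricModel()
  s <- m@sigmaLog
  e <- biomassErrorPerTree(1000, 0.24, m)
  expect_equal(e$sigmaMDbh, 1000 * 2.4814 * 0.24, tolerance = 1e-12)
  expect_equal(e$sigmaAllom,
               1000 * exp(s^2 / 2) * sqrt(exp(s^2) - 1), tolerance = 1e-12)
  # identical to the lognormal moment form sqrt(exp(2s^2+2mu) - exp(s^2+2mu))
  mu <- log(1000)
  expect_equal(e$sigmaAllom,
               sqrt(exp(2 * s^2 + 2 * mu) - exp(s^2 + 2 * mu)),
               tolerance = 1e-9)
  expect_equal(e$sigmaAgb, sqrt(e$sigmaMDbh^2 + e$sigmaAllom^2))

  none <- biomassErrorPerTree(1000, 0, allometricModel(sigmaLog = 0))
  expect_equal(none$sigmaAgb, 0)

  # amplification through the exponent: 24% DBH error -> ~60% biomass error
  expect_equal(round(100 * e$sigmaMDbh / 1000), 60)
  expect_equal(round(100 * allometricFitCV(m)), 18)
})

test_that("the error budget is monotone and internally consistent", {
  m <- allometricModel(sigmaA = 0.14, rmseDbh = 15.5)
  b <- errorBudget(c(10, 20, 30, 50), m, sigmaHt = 2)
  pt <- b@perTree
  expect_true(all(pt$sigmaAgb >= pt$sigmaMDbh))
  expect_true(all(pt$sigmaAgb >= pt$sigmaAllom))
  expect_equal(b@total, sum(pt$biomass))
  expect_equal(b@sigmaTotal, sum(pt$sigmaAgb))

  # increasing any error source strictly increases sigma_agb
  b2 <- errorBudget(c(10, 20, 30, 50), m, sigmaHt = 3)
  expect_true(all(b2@perTree$sigmaAgb > pt$sigmaAgb))
  m3 <- allometricModel(sigmaA = 0.2, rmseDbh = 15.5)
  b3 <- errorBudget(c(10, 20, 30, 50), m3, sigmaHt = 2)
  expect_true(all(b3@perTree$sigmaAgb > pt$sigmaAgb))
})

test_that("epoch totals aggregate and reproduce printed-style arithmetic", {
  agg <- aggregateTotals(359.67, 208.53, 285.09, 172.73)
  expect_equal(agg$agbChange, -74.58, tolerance = 1e-9)
  expect_equal(agg$sigmaChange, 62.54, tolerance = 1e-3)
  expect_equal(round(100 * agg$frac_1), 58)
  expect_equal(round(100 * agg$frac_2), 61)

  same <- aggregateTotals(c(10, 20), c(1, 2), c(10, 20), c(1, 2))
  expect_equal(same$agbChange, 0)
  expect_equal(same$sigmaChange, 0)

  one <- aggregateTotals(10, 2, 8, 1.5, totalMethod = "linear")
  oneR <- aggregateTotals(10, 2, 8, 1.5, totalMethod = "rss")
  expect_equal(one$sigmaTotal_1, oneR$sigmaTotal_1)

  lin <- aggregateTotals(359.67, 208.53, 285.09, 172.73,
                         changeMethod = "linear")
  expect_gt(lin$sigmaChange, agg$sigmaChange)
  expect_error(aggregateTotals(numeric(), numeric(), 1, 1), "nonempty")
})

test_that("Monte-Carlo draws agree with the analytic chain", {
  m <- allometricModel(sigmaA = 0.063 * 2.2, rmseDbh = 15.5)
  h <- 30
  dbh <- predictDbh(h, m)
  M <- jenkinsBiomass(dbh, m)

  zero <- monteCarloErrorOracle(h, allometricModel(sigmaA = 0, rmseDbh = 0,
                                                   sigmaLog = 0),
                                sigmaHt = 0, nDraws = 2000, seed = 1)
  expect_equal(zero$biomassSd, 0)

  # sources that enter the DBH linearly: exact at the DBH stage (2%)
  hts <- monteCarloErrorOracle(h, m, sigmaHt = 2.31, nDraws = 1e5, seed = 2,
                               sources = "height")
  expect_lt(abs(hts$dbhSd - m@a * 2.31) / (m@a * 2.31), 0.02)
  par <- monteCarloErrorOracle(h, m, sigmaHt = 0, nDraws = 1e5, seed = 3,
                               sources = "param")
  expect_lt(abs(par$dbhSd - m@sigmaA * h) / (m@sigmaA * h), 0.02)
  res <- monteCarloErrorOracle(h, m, sigmaHt = 0, nDraws = 1e5, seed = 4,
                               sources = "resid")
  expect_lt(abs(res$dbhSd - m@rmseDbh) / m@rmseDbh, 0.02)

  # lognormal allometric scatter: exact at the biomass stage (2%)
  al <- monteCarloErrorOracle(h, m, sigmaHt = 0, nDraws = 1e5, seed = 5,
                              sources = "allom")
  cv <- al$biomassSd / al$biomassMean
  expect_lt(abs(cv - allometricFitCV(m)) / allometricFitCV(m), 0.02)
})
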