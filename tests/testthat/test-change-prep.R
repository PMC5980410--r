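test_that("scan-angle filtering keeps the inclusive boundary", {
  cl <- data.frame(x = 1:6, y = 1, z = 1,
                   scan_angle = c(-20, -15, 0, 14.9, 15, 16))
  expect_equal(filterScanAngle(cl)$scan_angle, c(-15, 0, 14.9, 15))
  expect_equal(filterScanAngle(cl, maxAngle = 0)$scan_angle, 0)

  set.seed(2)
  big <- data.frame(x = 0, y = 0, z = 0, scan_angle = runif(1e5, -25, 25))
  frac <- nrow(filterScanAngle(big)) / 1e5
  expect_lt(abs(frac - 30 / 50), 3 * sqrt(0.6 * 0.4 / 1e5))
})

test_that("density equalisation thins the denser cloud only", {
  set.seed(4)
  c1 <- data.frame(x = runif(20000, 0, 100), y = runif(20000, 0, 100),
                   z = 0, scan_angle = 0)
  c2 <- data.frame(x = runif(10000, 0, 100), y = runif(10000, 0, 100),
                   z = 0, scan_angle = 0)
  eq <- equalizeDensity(c1, c2, seed = 1)
  expect_equal(nrow(eq$cloud2), 10000L)
  expect_lt(abs(nrow(eq$cloud1) - 10000), 4 * sqrt(10000 * 0.5))
  expect_equal(attr(eq, "kept")[2], 1)
})

test_that("affine registration recovers exact and noisy transforms", {
  set.seed(5)
  g <- data.frame(src_x = runif(50, 0, 500), src_y = runif(50, 0, 500))
  g$dst_x <- g$src_x + 1.2
  g$dst_y <- g$src_y - 0.7
  tf <- fitRegistration(g)
  expect_lt(max(abs(tf@b - c(1.2, -0.7))), 1e-9)
  expect_lt(max(abs(tf@A - diag(2))), 1e-9)
  expect_lt(tf@rmse, 1e-9)

  ident <- data.frame(src_x = g$src_x, src_y = g$src_y,
                      dst_x = g$src_x, dst_y = g$src_y)
  ti <- fitRegistration(ident)
  expect_lt(max(abs(ti@A - diag(2))), 1e-12)
  expect_lt(ti@rmse, 1e-12)

  noisy <- g
  noisy$dst_x <- noisy$dst_x + rnorm(50, 0, 0.3)
  noisy$dst_y <- noisy$dst_y + rnorm(50, 0, 0.3)
  tn <- fitRegistration(noisy)
  expect_gt(tn@rmse, 0.15); expect_lt(tn@rmse, 0.45)

  expect_error(fitRegistration(g[1:2, ]), "at least 3")
  coll <- data.frame(src_x = 1:5, src_y = 2 * (1:5), dst_x = 1:5,
                     dst_y = 2 * (1:5))
  expect_error(fitRegistration(coll), "collinear")
})

test_that("transforms apply to tables and grids and invert cleanly", {
  tf <- affineTransform(A = matrix(c(1, 0.01, -0.01, 1), 2), b = c(3, -2))
  pts <- data.frame(x = runif(20, 0, 10), y = runif(20, 0, 10))
  fwd <- applyTransform(pts, tf)
  back <- applyTransform(fwd, invertTransform(tf))
  expect_lt(max(abs(back$x - pts$x)), 1e-9)
  expect_lt(max(abs(back$y - pts$y)), 1e-9)

  # identity leaves a grid untouched
  lab <- matrix(0, 12, 12); lab[4:6, 4:6] <- 3
  g <- surfaceGrid(lab, c(0, 0), 0.5, "LABELS")
  same <- applyTransform(g, affineTransform())
  expect_equal(gridValues(same), lab)

  # translation by exactly one cell shifts the raster by one cell
  shifted <- applyTransform(g, affineTransform(b = c(0.5, 0)))
  expect_equal(gridValues(shifted)[, 5:7], lab[, 4:6])
})

test_that("centroid-overlay matching links identical epochs one to one", {
  v <- bumpSurface(seed = 6)
  chm <- chmGrid(v, res = 1)
  labs <- watershedSegment(chm, minTreeHeight = 2)
  crowns <- extractAttributes(labs, chm)
  m <- matchCrowns(crowns, labs, crowns, labels1 = labs)
  expect_equal(nrow(m), nrow(crowns))
  expect_equal(m$d_height, rep(0, nrow(m)))
  expect_equal(m$d_radius, rep(0, nrow(m)))
  expect_true(all(m$reciprocal))
  expect_equal(attr(m, "n_unmatched"), 0L)

  # a crown erased from epoch 2 drops out and is counted
  lv <- gridValues(labs)
  gone <- crowns$id[1]
  lv[lv == gone] <- 0
  labs2 <- surfaceGrid(lv, gridOrigin(labs), gridResolution(labs), "LABELS")
  m2 <- matchCrowns(crowns, labs2, crowns[crowns$id != gone, ],
                    labels1 = labs)
  expect_false(gone %in% m2$id_1)
  expect_equal(attr(m2, "n_unmatched"), 1L)
})

test_that("the four growth filters use strict thresholds", {
  base <- data.frame(id_1 = 1:7, id_2 = 1:7,
                     height_1 = 20, height_2 = 20,
                     radius_1 = 2, radius_2 = 2,
                     d_height = c(0, 5.2, 5.0, 4.999, 0, 0, 0),
                     d_radius = c(0, 0, 0, 0, 0, 2.1, 1.9),
                     d_dem = c(0.99, 0, 0, 0, 1.0, 0, 0),
                     reciprocal = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  f <- applyGrowthFilters(base)
  kept <- f$matches$id_1
  expect_true(1 %in% kept)          # d_dem 0.99 retained ("less than 1 m")
  expect_false(2 %in% kept)         # 5.2 m height change
  expect_false(3 %in% kept)         # exactly 5 m: strict
  expect_true(4 %in% kept)
  expect_false(5 %in% kept)         # exactly 1 m DEM difference: strict
  expect_false(6 %in% kept)         # 105% radius change
  expect_true(7 %in% kept)          # 95% radius change
  expect_equal(f$counts$n_in, 7L)

  norecip <- base; norecip$reciprocal[1] <- FALSE
  f2 <- applyGrowthFilters(norecip)
  expect_false(1 %in% f2$matches$id_1)
  f3 <- applyGrowthFilters(norecip, requireReciprocal = FALSE)
  expect_true(1 %in% f3$matches$id_1)
})

test_that("filters commute: joint retention equals the intersection", {
  set.seed(7)
  n <- 300
  m <- data.frame(id_1 = 1:n, id_2 = 1:n,
                  height_1 = runif(n, 5, 60), height_2 = 0,
                  radius_1 = runif(n, 1, 6), radius_2 = 0,
                  d_height = rnorm(n, 0, 4),
                  d_radius = rnorm(n, 0, 2),
                  d_dem = abs(rnorm(n, 0, 0.8)),
                  reciprocal = runif(n) > 0.1)
  joint <- applyGrowthFilters(m)$matches$id_1
  only <- function(...) applyGrowthFilters(m, ...)$matches$id_1
  f1 <- only(maxDHeight = Inf, maxDDem = Inf, maxRadiusChange = Inf)
  f2 <- only(maxDDem = Inf, maxRadiusChange = Inf, requireReciprocal = FALSE)
  f3 <- only(maxDHeight = Inf, maxRadiusChange = Inf,
             requireReciprocal = FALSE)
  f4 <- only(maxDHeight = Inf, maxDDem = Inf, requireReciprocal = FALSE)
  expect_setequal(joint, Reduce(intersect, list(f1, f2, f3, f4)))
})

test_that("threshold sweeps reduce to the defaults and to no filtering", {
  set.seed(8)
  n <- 200
  m <- data.frame(id_1 = 1:n, id_2 = 1:n,
                  height_1 = runif(n, 5, 60), height_2 = 0,
                  radius_1 = runif(n, 1, 6), radius_2 = 0,
                  d_height = rnorm(n, 0.5, 2), d_radius = rnorm(n, 0, 1.5),
                  d_dem = abs(rnorm(n, 0, 0.6)), reciprocal = TRUE)
  sw <- filterSensitivitySweep(
    m, data.frame(maxDHeight = c(5, Inf), maxDDem = c(1, Inf),
                  maxRadiusChange = c(1, Inf)), minN = 10)
  expect_equal(sw$combos$n[1], nrow(applyGrowthFilters(m)$matches))
  expect_equal(sw$combos$n[2], n)
  expect_error(filterSensitivitySweep(m, data.frame()), "empty")
})
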