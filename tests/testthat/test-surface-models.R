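test_that("a treeless scene classifies everything as ground", {
  set.seed(1)
  cl <- data.frame(x = runif(3000, 0, 40), y = runif(3000, 0, 40))
  cl$z <- 100 + 0.01 * cl$x
  g <- classifyGround(cl)
  expect_equal(nrow(g), nrow(cl))
})

test_that("crown returns stay out of the ground set", {
  sc <- oneTree(h = 20, r = 3, extent = c(40, 40))
  cl <- simulateAcquisition(sc, cleanSpec(density = 30))
  g <- classifyGround(cl)
  expect_lt(max(g$z - sc$terrain(g$x, g$y)), 0.5)
})

test_that("DEM interpolation is exact on planar input", {
  set.seed(2)
  pts <- data.frame(x = runif(1000, 0, 50), y = runif(1000, 0, 50))
  pts$z <- 0.01 * pts$x + 5
  dem <- buildDEM(pts, resolution = 1)
  v <- gridValues(dem)
  d <- dim(v)
  ctr <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  x <- gridOrigin(dem)[1] + (ctr$col - 0.5) * gridResolution(dem)
  truth <- 0.01 * x + 5
  err <- abs(v[cbind(ctr$row, ctr$col)] - truth)
  expect_lt(max(err, na.rm = TRUE), 1e-6)
  expect_gt(sum(is.finite(v)), 0.9 * length(v))
})

test_that("three points give an exact plane; degenerate input errors", {
  tri <- data.frame(x = c(0, 10, 0), y = c(0, 0, 10), z = c(1, 2, 3))
  dem <- buildDEM(tri, resolution = 1)
  v <- gridValues(dem)
  # interior cell (2,2) centre (1.5, 1.5): z = 1 + 0.1*x + 0.2*y
  expect_equal(v[2, 2], 1 + 0.1 * 1.5 + 0.2 * 1.5, tolerance = 1e-9)
  expect_true(is.na(v[nrow(v), ncol(v)]))  # outside the triangle

  flat <- data.frame(x = c(0, 10, 0, 10), y = c(0, 0, 10, 10), z = 7)
  demf <- buildDEM(flat, resolution = 1)
  expect_equal(range(gridValues(demf), na.rm = TRUE), c(7, 7))

  line <- data.frame(x = 1:5, y = 1:5, z = 1:5)
  expect_error(buildDEM(line), "collinear")
  expect_error(buildDEM(tri[1:2, ]), "at least 3")
})

test_that("DEM recovers the generator's terrain within 0.25 m RMSE", {
  sc <- generateScene(60, extent = c(80, 80), terrainRelief = 3, seed = 9)
  cl <- simulateAcquisition(sc, acquisitionSpec(returnDensity = 18, seed = 9))
  dem <- buildDEM(classifyGround(cl), resolution = 0.5)
  v <- gridValues(dem)
  d <- dim(v)
  ctr <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  x <- gridOrigin(dem)[1] + (ctr$col - 0.5) * 0.5
  y <- gridOrigin(dem)[2] + (ctr$row - 0.5) * 0.5
  err <- v[cbind(ctr$row, ctr$col)] - sc$terrain(x, y)
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 0.25)
})

test_that("CHM rasterisation, pit fill and clamping behave as stated", {
  # hand-built cloud on a flat DEM: exact expectations, no smoothing/splat
  dem <- surfaceGrid(matrix(100, 4, 4), c(0, 0), 1, "DEM")
  cl <- data.frame(x = c(0.5, 0.5, 2.5, 3.5), y = c(0.5, 1.5, 2.5, 0.5),
                   z = c(105, 99, 112, 100.4))
  chm <- buildCHM(cl, dem, smoothingSigma = 0, splatRadius = 0)
  v <- gridValues(chm)
  expect_equal(v[1, 1], 5)        # max z - dem
  expect_equal(v[2, 1], 0)        # negative clamped
  expect_equal(v[3, 3], 12)
  expect_equal(v[1, 4], 0.4)
  # empty cell with occupied neighbours takes their median, else 0
  expect_equal(v[2, 2], median(c(5, 0, 12)))
  expect_equal(v[4, 1], 0)
})

test_that("a clean single tree yields a CHM peak at its height", {
  sc <- oneTree(h = 30, r = 4, extent = c(30, 30))
  cl <- simulateAcquisition(sc, cleanSpec(density = 60))
  dem <- buildDEM(classifyGround(cl), resolution = 0.5)
  chm <- buildCHM(cl, dem, smoothingSigma = 0)
  expect_lt(abs(max(gridValues(chm), na.rm = TRUE) - 30), 0.6)
})

test_that("smoothing is an averaging kernel: never raises the maximum", {
  sc <- generateScene(10, extent = c(40, 40), seed = 3)
  cl <- simulateAcquisition(sc, acquisitionSpec(returnDensity = 12, seed = 3))
  dem <- buildDEM(classifyGround(cl), resolution = 0.5)
  raw <- buildCHM(cl, dem, smoothingSigma = 0)
  sm <- buildCHM(cl, dem, smoothingSigma = 0.75)
  expect_lte(max(gridValues(sm), na.rm = TRUE),
             max(gridValues(raw), na.rm = TRUE) + 1e-9)
  # DEM + CHM bounds every return in occupied cells (no smoothing)
  demv <- gridValues(dem); chmv <- gridValues(raw)
  idx <- canopychange:::.cell_index(dem, cl$x, cl$y)
  ok <- !is.na(idx$row)
  top <- demv[cbind(idx$row[ok], idx$col[ok])] +
    chmv[cbind(idx$row[ok], idx$col[ok])]
  expect_true(all(top + 1e-6 >= cl$z[ok] |
                  !is.finite(top)))
})

test_that("the CHM is translation-equivariant over whole cells", {
  set.seed(8)
  n <- 4000
  cl <- data.frame(x = runif(n, 1, 19), y = runif(n, 1, 19),
                   z = 100 + 5 * sin(runif(n, 0, 6)))
  dem <- surfaceGrid(matrix(100, 40, 40), c(0, 0), 0.5, "DEM")
  a <- buildCHM(cl, dem, smoothingSigma = 0)
  clShift <- transform(cl, x = x + 0.5)
  b <- buildCHM(clShift, dem, smoothingSigma = 0)
  va <- gridValues(a); vb <- gridValues(b)
  # interior columns shift by exactly one cell
  expect_equal(vb[, 4:39], va[, 3:38])
})

test_that("differencing is exact, linear, and strict about alignment", {
  m1 <- matrix(10.18, 10, 10); m2 <- matrix(11.73, 10, 10)
  c1 <- chmGrid(m1); c2 <- chmGrid(m2)
  d <- differenceCHM(c1, c2)
  expect_equal(gridKind(d), "DIFF")
  expect_equal(unique(as.vector(gridValues(d))), 10.18 - 11.73)

  expect_equal(gridValues(differenceCHM(c1, c1)),
               matrix(0, 10, 10))
  # linearity: mean(chm2) - mean(chm1) = -mean(diff)
  set.seed(1)
  r1 <- chmGrid(matrix(runif(100, 0, 30), 10, 10))
  r2 <- chmGrid(matrix(runif(100, 0, 30), 10, 10))
  dd <- differenceCHM(r1, r2)
  expect_equal(mean(gridValues(r2)) - mean(gridValues(r1)),
               -mean(gridValues(dd)))

  off <- surfaceGrid(m2, c(1, 0), 0.5, "CHM")
  expect_error(differenceCHM(c1, off), "not aligned")

  # nodata propagates, never becomes zero
  m1na <- m1; m1na[3, 3] <- NA
  dna <- differenceCHM(chmGrid(m1na), c2)
  expect_true(is.na(gridValues(dna)[3, 3]))
})
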