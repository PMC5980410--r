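test_that("two separated trees give two crowns with centroids at the stems", {
  sc <- manualScene(data.frame(id = 1:2, x = c(20, 40), y = c(25, 25),
                               height = c(20, 18), crown_radius = c(3, 3)),
                    extent = c(60, 50))
  cl <- simulateAcquisition(sc, cleanSpec(density = 40))
  dem <- buildDEM(classifyGround(cl), resolution = 0.5)
  chm <- buildCHM(cl, dem)
  labs <- watershedSegment(chm)
  at <- extractAttributes(labs, chm)
  expect_equal(nrow(at), 2L)
  ord <- order(at$x)
  expect_lt(abs(at$x[ord[1]] - 20), 1); expect_lt(abs(at$y[ord[1]] - 25), 1)
  expect_lt(abs(at$x[ord[2]] - 40), 1); expect_lt(abs(at$y[ord[2]] - 25), 1)
})

test_that("watershed background and empty cases are handled", {
  low <- chmGrid(matrix(1.2, 20, 20))
  expect_equal(max(gridValues(watershedSegment(low, minTreeHeight = 2))), 0)

  one <- oneTree(h = 15, r = 3, extent = c(30, 30))
  cl <- simulateAcquisition(one, cleanSpec(density = 40))
  dem <- buildDEM(classifyGround(cl), resolution = 0.5)
  chm <- buildCHM(cl, dem)
  labs <- watershedSegment(chm)
  expect_equal(max(gridValues(labs), na.rm = TRUE), 1)
})

test_that("every canopy cell carries exactly one layer-0 label", {
  v <- bumpSurface(seed = 4)
  labs <- gridValues(watershedSegment(chmGrid(v, res = 1), minTreeHeight = 2))
  mask <- v >= 2
  expect_true(all(labs[mask] > 0))
  expect_true(all(labs[!mask] == 0))
})

test_that("watershed assignment matches the brute-force ascent oracle", {
  for (seed in 1:3) {
    v <- bumpSurface(seed = seed)
    labs <- gridValues(watershedSegment(chmGrid(v, res = 1),
                                        minTreeHeight = 2))
    term <- steepestOracle(v, 2)
    sel <- term > 0
    # the label partition must equal the oracle's terminal partition
    expect_equal(length(unique(labs[sel])), length(unique(term[sel])))
    grouping <- tapply(labs[sel], term[sel], function(x) length(unique(x)))
    expect_true(all(grouping == 1))
  }
})

test_that("crown attributes follow their closed forms", {
  lab <- matrix(0, 10, 10)
  lab[3:6, 3:6] <- 1          # 16 cells at 0.5 m resolution
  lab[9, 9] <- 2
  chm <- matrix(1, 10, 10); chm[4, 4] <- 8; chm[9, 9] <- 3
  at <- extractAttributes(surfaceGrid(lab, c(0, 0), 0.5, "LABELS"),
                          chmGrid(chm))
  expect_equal(at$area[1], 4)
  expect_equal(at$radius[1], sqrt(4 / pi))
  expect_equal(at$height[1], 8)
  expect_equal(at$x[1], (mean(3:6) - 0.5) * 0.5)
  # single-cell segment sits at its cell centre
  expect_equal(at$x[2], (9 - 0.5) * 0.5)
  expect_equal(at$y[2], (9 - 0.5) * 0.5)
  expect_true(all(at$height <= max(chm)))
})

test_that("the vertical gap rule splits layered segments only", {
  set.seed(5)
  single <- runif(200, 10, 20)         # one continuous crown
  expect_false(classifyLayers(single)$split)

  column <- runif(400, 1, 30)          # uniform vertical column: no gap
  expect_false(classifyLayers(column)$split)

  layered <- c(runif(120, 15, 30), runif(30, 2, 8))
  res <- classifyLayers(layered)
  expect_true(res$split)
  expect_gt(res$splitHeight, 8); expect_lt(res$splitHeight, 15)
  expect_equal(sum(res$understory), 30)

  expect_false(classifyLayers(layered[c(1:4, 121:124)])$split)  # too few
})

test_that("an understory tree under a dominant crown yields a second layer", {
  sc <- manualScene(data.frame(id = 1:2, x = c(20, 23.5), y = c(20, 20),
                               height = c(30, 10), crown_radius = c(5, 2)),
                    extent = c(40, 40))
  cl <- simulateAcquisition(sc, acquisitionSpec(returnDensity = 50,
                                                footprintDiameter = 0,
                                                verticalNoiseSd = 0,
                                                groundFraction = 0.35,
                                                seed = 1))
  dem <- buildDEM(classifyGround(cl), resolution = 0.5)
  chm <- buildCHM(cl, dem)
  # an occluded understory is a small share of in-segment returns, so the
  # split-fraction guard is lowered for this geometry
  del <- delineateMultistory(chm, cl, dem, minFraction = 0.015)
  expect_equal(del$nLayers, 2L)
  under <- del$crowns[del$crowns$layer == 1L, ]
  expect_gte(nrow(under), 1L)
  best <- under[which.min((under$x - 23.5)^2 + (under$y - 20)^2), ]
  expect_lt(abs(best$height - 10), 2.5)
  # the split sits in the gap between understory top and overstory base
  expect_false(any(del$crowns$layer == 1L & del$crowns$height > 15))
})

test_that("delineation recovers a 200-tree stand with 10% understory", {
  over <- generateScene(180, extent = c(170, 170), seed = 21)
  tr <- over$trees
  # plant 20 understory trees under the edges of the 20 largest crowns
  host <- tr[order(-tr$height)[1:20], ]
  und <- data.frame(id = 180L + 1:20,
                    x = host$x + 0.6 * host$crown_radius, y = host$y,
                    height = pmax(4, 0.35 * host$height),
                    crown_radius = pmax(0.8, 0.3 * host$crown_radius))
  sc <- manualScene(rbind(tr, und), extent = c(170, 170),
                    terrain = over$terrain)
  cl <- simulateAcquisition(sc, acquisitionSpec(returnDensity = 18,
                                                seed = 22))
  dem <- buildDEM(classifyGround(cl), resolution = 0.5)
  chm <- buildCHM(cl, dem)
  del <- delineateMultistory(chm, cl, dem)
  expect_lt(abs(nrow(del$crowns) - 200) / 200, 0.15)

  # height RMSE of isolated dominants (layer 0 matched within 1.5 m)
  lay0 <- del$crowns[del$crowns$layer == 0L, ]
  nn <- vapply(seq_len(nrow(lay0)), function(i) {
    d2 <- (tr$x - lay0$x[i])^2 + (tr$y - lay0$y[i])^2
    j <- which.min(d2)
    if (d2[j] < 2.25) tr$height[j] else NA_real_
  }, numeric(1))
  err <- lay0$height - nn
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 1)

  # reruns are bit-identical
  del2 <- delineateMultistory(chm, cl, dem)
  expect_identical(del$crowns, del2$crowns)
})

test_that("well-separated stands are recovered tree for tree", {
  sc <- generateScene(30, extent = c(130, 130), seed = 31,
                      spacingFactor = 1.6,
                      heightDistribution = list(type = "uniform", minh = 8,
                                                maxh = 40, min = 8, max = 40))
  cl <- simulateAcquisition(sc, acquisitionSpec(returnDensity = 18, seed = 32))
  dem <- buildDEM(classifyGround(cl), resolution = 0.5)
  chm <- buildCHM(cl, dem)
  del <- delineateMultistory(chm, cl, dem)
  lay0 <- del$crowns[del$crowns$layer == 0L, ]
  expect_equal(nrow(lay0), 30L)
  nn <- vapply(seq_len(nrow(lay0)), function(i) {
    d2 <- (sc$trees$x - lay0$x[i])^2 + (sc$trees$y - lay0$y[i])^2
    sc$trees$height[which.min(d2)]
  }, numeric(1))
  expect_lt(abs(mean(lay0$height - nn)), 0.5)
})
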