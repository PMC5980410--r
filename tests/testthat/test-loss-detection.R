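test_that("difference segmentation ignores flat and growth-only surfaces", {
  zero <- surfaceGrid(matrix(0, 20, 20), c(0, 0), 0.5, "DIFF")
  expect_equal(nrow(segmentDifference(zero)$segments), 0L)

  grown <- surfaceGrid(matrix(-1.5, 20, 20), c(0, 0), 0.5, "DIFF")
  expect_equal(nrow(segmentDifference(grown)$segments), 0L)
})

test_that("a removed tree appears as one difference segment at its height", {
  sc1 <- manualScene(data.frame(id = 1:3, x = c(15, 35, 25), y = c(15, 35, 30),
                                height = c(25, 18, 12),
                                crown_radius = c(3.5, 2.8, 2)),
                     extent = c(50, 50))
  sc2 <- manualScene(sc1$trees[-1, ], extent = c(50, 50))
  cl1 <- simulateAcquisition(sc1, cleanSpec(density = 40, seed = 1))
  cl2 <- simulateAcquisition(sc2, cleanSpec(density = 40, seed = 2))
  dem <- buildDEM(classifyGround(cl1), resolution = 0.5)
  chm1 <- buildCHM(cl1, dem)
  chm2 <- buildCHM(cl2, dem)
  ds <- segmentDifference(differenceCHM(chm1, chm2))
  expect_equal(nrow(ds$segments), 1L)
  expect_lt(abs(ds$segments$height - 25), 2)
  expect_lt(abs(ds$segments$x - 15), 1.5)

  # and it is matched to the 2008 crown as a loss event
  labs1 <- watershedSegment(chm1)
  crowns1 <- extractAttributes(labs1, chm1)
  ev <- matchLoss(ds, crowns1, labs1, chm1 = chm1)
  expect_equal(nrow(ev), 1L)
  expect_lt(ev$height_delta_match, 3)
  expect_lt(ev$area_ratio_delta, 0.30)
})

test_that("loss matching applies strict 3 m / 30% thresholds", {
  d <- diskGrids(height = 10)
  crowns1 <- extractAttributes(d$labels, d$chm)

  runCase <- function(diffHeight, radius = 6) {
    dd <- diskGrids(height = diffHeight, radius = radius)
    diffGrid <- surfaceGrid(gridValues(dd$chm), c(0, 0), 0.5, "DIFF")
    matchLoss(segmentDifference(diffGrid), crowns1, d$labels, chm1 = d$chm)
  }
  expect_equal(nrow(runCase(10)), 1L)        # exact reproduction
  expect_equal(nrow(runCase(7.1)), 1L)       # height delta 2.9 m
  expect_equal(nrow(runCase(6.9)), 0L)       # height delta 3.1 m
  expect_equal(nrow(runCase(7.0)), 0L)       # exactly 3 m: strict

  full <- nrow(segmentDifference(surfaceGrid(gridValues(d$chm), c(0, 0),
                                             0.5, "DIFF"))$segments)
  expect_equal(full, 1L)
  # area within / beyond 30% of the crown's area
  aFull <- d$area
  rOk <- 6 * sqrt(0.75)     # ~25% smaller area
  rBad <- 6 * sqrt(0.62)    # ~38% smaller area
  expect_equal(nrow(runCase(10, radius = rOk)), 1L)
  expect_equal(nrow(runCase(10, radius = rBad)), 0L)
})

test_that("edge slivers are rejected by the area filter", {
  d <- diskGrids(height = 10)
  sliver <- matrix(0, 40, 40)
  sliver[20, 14:16] <- 9.5    # 3-cell sliver at the crown edge
  diffGrid <- surfaceGrid(sliver, c(0, 0), 0.5, "DIFF")
  ev <- matchLoss(segmentDifference(diffGrid),
                  extractAttributes(d$labels, d$chm), d$labels, chm1 = d$chm)
  expect_equal(nrow(ev), 0L)
})

test_that("no 2008 crown is double-counted across difference segments", {
  d <- diskGrids(height = 10)
  two <- matrix(0, 40, 40)
  two[16:19, 16:24] <- 9.8    # two separate pieces over the same crown
  two[21:24, 16:24] <- 9.6
  diffGrid <- surfaceGrid(two, c(0, 0), 0.5, "DIFF")
  ds <- segmentDifference(diffGrid)
  ev <- matchLoss(ds, extractAttributes(d$labels, d$chm), d$labels,
                  chm1 = d$chm, areaTol = 10)  # disable area filter
  expect_lte(sum(ev$id_1 == 1), 1L)
})

test_that("loss rates by class follow their definitions", {
  crowns <- data.frame(id = 1:100, layer = 0L, x = 0, y = 0, area = 10,
                       radius = 1.8,
                       height = rep(c(7, 12, 22, 40), each = 25))
  none <- lossRateByClass(data.frame(id_1 = integer(),
                                     diff_segment_id = integer(),
                                     height_delta_match = numeric(),
                                     area_ratio_delta = numeric(),
                                     height_1 = numeric()), crowns)
  expect_true(all(none$byClass$rate == 0))
  expect_equal(none$overall, 0)

  all_ev <- data.frame(id_1 = crowns$id, diff_segment_id = crowns$id,
                       height_delta_match = 0, area_ratio_delta = 0,
                       height_1 = crowns$height)
  full <- lossRateByClass(all_ev, crowns)
  expect_true(all(full$byClass$rate == 1))
  expect_equal(full$overall, 1)

  some <- lossRateByClass(all_ev[1:13, ], crowns, intervalYears = 5)
  expect_equal(some$overall, 0.13)
  expect_equal(some$annualLinear, 0.13 / 5)
  expect_equal(some$annualCompound, 1 - (1 - 0.13)^(1 / 5))
})

test_that("count-based loss reproduces simple bookkeeping", {
  cb <- countBasedLoss(87913, 79078)
  expect_equal(cb$difference, 8835)
  expect_equal(round(100 * cb$fraction), 10)
  expect_equal(countBasedLoss(50, 50)$difference, 0)
  gain <- countBasedLoss(40, 55)
  expect_equal(gain$difference, -15)
  expect_lt(gain$fraction, 0)
})
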