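# shared fixture builders; everything is generated in code at test time

# a ForestScene with explicit trees and flat (or supplied) terrain,
# bypassing the placement sampler
manualScene <- function(trees, extent = c(50, 50), terrain = NULL,
                        crownBaseRatio = 0.5, base = 100) {
  if (is.null(terrain)) terrain <- function(x, y) rep(base, length(x))
  structure(list(trees = trees, terrain = terrain, extent = extent,
                 crownBaseRatio = crownBaseRatio),
            class = "ForestScene")
}

oneTree <- function(h = 30, r = 4, x = 25, y = 25, extent = c(50, 50)) {
  manualScene(data.frame(id = 1L, x = x, y = y, height = h,
                         crown_radius = r), extent = extent)
}

# dense, noise-free acquisition for geometric checks
cleanSpec <- function(density = 60, seed = 1) {
  acquisitionSpec(returnDensity = density, footprintDiameter = 0,
                  verticalNoiseSd = 0, groundFraction = 0, seed = seed)
}

idScenario <- function(seed = 1) {
  changeScenario(growthRateFn = function(h) rep(0, length(h)), growthSd = 0,
                 removalProbFn = function(h) rep(0, length(h)), seed = seed)
}

# flat synthetic CHM grid from a matrix
chmGrid <- function(m, res = 0.5, origin = c(0, 0)) {
  surfaceGrid(m, origin = origin, resolution = res, kind = "CHM")
}

# smooth two-bump test surface with no exact ties away from the background
bumpSurface <- function(nr = 40, nc = 40, seed = 1) {
  set.seed(seed)
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  v <- 9 * exp(-((rr - 12)^2 + (cc - 14)^2) / 30) +
    11 * exp(-((rr - 28)^2 + (cc - 26)^2) / 40) +
    matrix(runif(nr * nc, 0, 1e-6), nr, nc)
  v
}

# independent brute-force oracle: follow the single steepest-ascent step to
# the 8-neighbour with the highest value (first such neighbour in ascending
# linear-index order) until reaching a cell with no higher neighbour; cells
# are grouped by terminal summit. Only valid on tie-free surfaces.
steepestOracle <- function(v, minH) {
  nr <- nrow(v); nc <- ncol(v)
  mask <- is.finite(v) & v >= minH
  terminal <- matrix(0L, nr, nc)
  step <- function(r, c) {
    best <- c(r, c); bestv <- v[r, c]
    for (dc in -1:1) for (dr in -1:1) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if ((dr | dc) && mask[r2, c2] && v[r2, c2] > bestv) {
        bestv <- v[r2, c2]; best <- c(r2, c2)
      }
    }
    best
  }
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (!mask[r, c]) next
    cur <- c(r, c)
    repeat {
      nxt <- step(cur[1], cur[2])
      if (all(nxt == cur)) break
      cur <- nxt
    }
    terminal[r, c] <- cur[1] + (cur[2] - 1L) * nr
  }
  terminal
}

# disk-shaped label/CHM pair for loss-matching tests
diskGrids <- function(nr = 40, nc = 40, centre = c(20, 20), radius = 6,
                      height = 10, res = 0.5) {
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  inside <- (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
  lab <- matrix(0, nr, nc); lab[inside] <- 1
  chm <- matrix(0, nr, nc); chm[inside] <- height
  list(labels = surfaceGrid(lab, c(0, 0), res, "LABELS"),
       chm = surfaceGrid(chm, c(0, 0), res, "CHM"),
       inside = inside, area = sum(inside) * res^2)
}
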