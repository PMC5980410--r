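#' Acquisition specification for a simulated lidar campaign
#'
#' Captures the instrument and flight characteristics that differ between the
#' two campaigns the package is designed around: a ~18 returns/m^2, 15 cm
#' footprint survey and a later ~13 returns/m^2, 10 cm footprint survey, both
#' scanning to at most 25 degrees off nadir, with a small horizontal
#' mis-registration between them.
#'
#' Scan angles are assigned from the horizontal distance to the nearest of a
#' set of parallel north-south flight lines flown at `altitude`; only the
#' magnitude of the angle matters downstream (the +/-15 degree filter). Lines
#' are spaced `lineSpacing` metres apart and centred on the scene, emulating
#' a survey with side lap, so most of the scene is seen well inside the
#' scanner's angular limit. Returns that would require an angle beyond
#' `maxScanAngle` from every line fall outside the swath and are not
#' generated.
#'
#' @param returnDensity mean returns per square metre (> 0).
#' @param footprintDiameter laser footprint diameter, metres. A larger
#'   footprint raises the odds of catching crown apices and edges: each
#'   return reports the highest point of the crown envelope within half a
#'   footprint of its nominal position.
#' @param maxScanAngle maximum off-nadir scan angle, degrees (0, 30].
#' @param horizontalOffset length-2 `(dx, dy)` systematic horizontal shift of
#'   reported coordinates, metres (the epoch-to-epoch mis-registration).
#' @param verticalNoiseSd per-return vertical (ranging) noise SD, metres.
#' @param groundFraction fraction of pulses over a crown that penetrate to
#'   the ground instead of returning from the envelope, in `[0, 1)`.
#' @param altitude flying altitude above ground, metres.
#' @param lineSpacing flight-line spacing, metres.
#' @param seed integer seed making the simulated cloud reproducible.
#' @return A list of class `AcquisitionSpec`.
#' @examples
#' spec <- acquisitionSpec(returnDensity = 18, footprintDiameter = 0.15)
#' @export
acquisitionSpec <- function(returnDensity = 18, footprintDiameter = 0.15,
                            maxScanAngle = 25, horizontalOffset = c(0, 0),
                            verticalNoiseSd = 0.1, groundFraction = 0.3,
                            altitude = 600, lineSpacing = 280, seed = 1L) {
  stopifnot(returnDensity > 0, footprintDiameter >= 0,
            maxScanAngle > 0, maxScanAngle <= 30,
            length(horizontalOffset) == 2, verticalNoiseSd >= 0,
            groundFraction >= 0, groundFraction < 1,
            altitude > 0, lineSpacing > 0)
  structure(list(
    returnDensity = returnDensity, footprintDiameter = footprintDiameter,
    maxScanAngle = maxScanAngle, horizontalOffset = as.numeric(horizontalOffset),
    verticalNoiseSd = verticalNoiseSd, groundFraction = groundFraction,
    altitude = altitude, lineSpacing = lineSpacing, seed = as.integer(seed)
  ), class = "AcquisitionSpec")
}

#' Change scenario linking tree size to growth and removal
#'
#' @param growthRateFn function mapping height (m) to mean height growth (m)
#'   over the observation interval.
#' @param growthSd between-tree SD of height growth, metres.
#' @param removalProbFn function mapping height (m) to the probability of the
#'   tree being removed (felled/harvested) during the interval; values must
#'   lie in `[0, 1]`.
#' @param radiusGrowthFn crown-radius growth as a function of height;
#'   `NULL` (the default) keeps radii consistent with the generator's
#'   radius-height allometry by growing each surviving crown's radius by
#'   0.15 times its height growth.
#' @param seed integer seed.
#' @return A list of class `ChangeScenario`.
#' @examples
#' sc <- changeScenario(function(h) 0.8 * pmax(0, 60 - h) / 50, 0.3,
#'                      function(h) 0.2 - 0.15 * pmin(1, pmax(0, (h - 10) / 50)))
#' @export
changeScenario <- function(growthRateFn = function(h) rep(0.5, length(h)),
                           growthSd = 0.3,
                           removalProbFn = function(h) rep(0.1, length(h)),
                           radiusGrowthFn = NULL, seed = 1L) {
  stopifnot(is.function(growthRateFn), is.function(removalProbFn),
            growthSd >= 0)
  p <- removalProbFn(seq(1, 100, by = 0.5))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("removalProbFn must return probabilities in [0, 1]", call. = FALSE)
  }
  structure(list(
    growthRateFn = growthRateFn, growthSd = growthSd,
    removalProbFn = removalProbFn, radiusGrowthFn = radiusGrowthFn,
    seed = as.integer(seed)
  ), class = "ChangeScenario")
}

# draw heights from a parameterised distribution spec
.draw_heights <- function(n, dist, seed_active = TRUE) {
  type <- dist$type %||% "lognormal"
  lo <- dist$min %||% 2
  hi <- dist$max %||% 75
  draw <- switch(type,
    lognormal = function(k) rlnorm(k, dist$meanlog %||% log(20),
                                   dist$sdlog %||% 0.45),
    uniform   = function(k) runif(k, dist$minh %||% lo, dist$maxh %||% hi),
    normal    = function(k) rnorm(k, dist$mean %||% 20, dist$sd %||% 8),
    constant  = function(k) rep(dist$value %||% 20, k),
    stop("unknown height distribution type: ", type, call. = FALSE)
  )
  out <- numeric(0)
  guard <- 0
  while (length(out) < n && guard < 50) {
    x <- draw(2L * n)
    out <- c(out, x[x >= lo & x <= hi])
    guard <- guard + 1
  }
  if (length(out) < n) {
    stop("height distribution rejects too many draws within [min, max]",
         call. = FALSE)
  }
  out[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# smooth band-limited terrain: sum of 2-4 low-frequency sinusoidal ridges,
# rescaled so total relief over the extent is exactly `relief`
.make_terrain <- function(extent, relief, base = 1500) {
  nWaves <- sample(2:4, 1)
  theta <- runif(nWaves, 0, pi)
  wl <- runif(nWaves, 0.8, 2.5) * max(extent)   # wavelengths >= extent scale
  phase <- runif(nWaves, 0, 2 * pi)
  amp <- runif(nWaves, 0.5, 1)
  raw <- function(x, y) {
    z <- 0
    for (i in seq_len(nWaves)) {
      u <- cos(theta[i]) * x + sin(theta[i]) * y
      z <- z + amp[i] * sin(2 * pi * u / wl[i] + phase[i])
    }
    z
  }
  # empirical relief over a probe grid, then rescale
  gx <- seq(0, extent[1], length.out = 60)
  gy <- seq(0, extent[2], length.out = 60)
  zz <- outer(gx, gy, raw)
  span <- diff(range(zz))
  scale <- if (span > 0 && relief > 0) relief / span else 0
  force(scale)
  function(x, y) base + scale * raw(x, y)
}

#' Generate a synthetic forest scene with known truth
#'
#' Places `nTrees` trees in a rectangular scene over a smooth, band-limited
#' terrain surface. Heights are drawn from a stated distribution; crown radii
#' follow the monotone allometry `radius = 0.15 * height + noise`. Trees are
#' placed tallest-first under a minimum-spacing rule (centre distance at
#' least `spacingFactor` times the sum of crown radii) so that dominant
#' crowns are mostly resolvable, as in an open mature conifer stand.
#'
#' @param nTrees number of trees (>= 1).
#' @param extent scene size `(width, depth)` in metres.
#' @param heightDistribution list describing the height distribution:
#'   `type` (`"lognormal"`, `"uniform"`, `"normal"`, `"constant"`) plus its
#'   parameters and truncation bounds `min`/`max`.
#' @param terrainRelief total terrain relief across the scene, metres.
#' @param seed integer seed; fixed seeds reproduce the scene bit for bit.
#' @param spacingFactor minimum centre distance as a multiple of the two
#'   crowns' summed radii.
#' @param radiusNoiseSd SD of the additive noise on the crown-radius
#'   allometry, metres.
#' @param crownBaseRatio crown base height as a fraction of tree height (the
#'   crown envelope is a vertical half-ellipsoid from the base to the apex).
#' @param maxAttempts placement attempts per tree before giving up.
#' @return A list of class `ForestScene`: `trees` (data.frame `id`, `x`, `y`,
#'   `height`, `crown_radius`), `terrain` (vectorised elevation function of
#'   `(x, y)`), `extent`, `crownBaseRatio`.
#' @examples
#' sc <- generateScene(20, extent = c(60, 60), seed = 7)
#' nrow(sc$trees)
#' @export
generateScene <- function(nTrees, extent = c(100, 100),
                          heightDistribution = list(type = "lognormal",
                                                    meanlog = log(20),
                                                    sdlog = 0.45,
                                                    min = 2, max = 75),
                          terrainRelief = 3, seed = 1L,
                          spacingFactor = 1.1, radiusNoiseSd = 0.3,
                          crownBaseRatio = 0.5, maxAttempts = 300L) {
  stopifnot(nTrees >= 1, length(extent) == 2, all(extent > 0),
            terrainRelief >= 0, spacingFactor >= 0)
  withr::with_seed(as.integer(seed), {
    terrain <- .make_terrain(extent, terrainRelief)
    h <- sort(.draw_heights(nTrees, heightDistribution), decreasing = TRUE)
    r <- 0.15 * h + rnorm(nTrees, 0, radiusNoiseSd)
    r <- pmin(0.79 * h, pmax(pmin(0.4, 0.79 * h), r))

    # sequential placement with a bucket grid for neighbour queries
    cellSz <- max(2 * spacingFactor * max(r), 1)
    nbx <- max(1L, ceiling(extent[1] / cellSz))
    nby <- max(1L, ceiling(extent[2] / cellSz))
    buckets <- vector("list", nbx * nby)
    px <- numeric(nTrees); py <- numeric(nTrees)
    for (i in seq_len(nTrees)) {
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        cx <- runif(1, 0, extent[1]); cy <- runif(1, 0, extent[2])
        bx <- pmin(nbx, pmax(1L, as.integer(cx / cellSz) + 1L))
        by <- pmin(nby, pmax(1L, as.integer(cy / cellSz) + 1L))
        near <- integer(0)
        for (ddx in -1:1) for (ddy in -1:1) {
          gx <- bx + ddx; gy <- by + ddy
          if (gx >= 1 && gx <= nbx && gy >= 1 && gy <= nby) {
            near <- c(near, buckets[[gx + (gy - 1L) * nbx]])
          }
        }
        ok <- TRUE
        if (length(near)) {
          d2 <- (px[near] - cx)^2 + (py[near] - cy)^2
          lim <- (spacingFactor * (r[near] + r[i]))^2
          ok <- all(d2 >= lim)
        }
        if (ok) {
          px[i] <- cx; py[i] <- cy
          buckets[[bx + (by - 1L) * nbx]] <- c(buckets[[bx + (by - 1L) * nbx]], i)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("extent too small to place ", nTrees,
             " trees at the minimum spacing (failed at tree ", i, ")",
             call. = FALSE)
      }
    }
    trees <- data.frame(id = seq_len(nTrees), x = px, y = py, height = h,
                        crown_radius = r)
    structure(list(trees = trees, terrain = terrain, extent = extent,
                   crownBaseRatio = crownBaseRatio),
              class = "ForestScene")
  })
}

#' Apply a change scenario to a scene
#'
#' Each tree is independently removed with probability
#' `removalProbFn(height)`; survivors grow by `growthRateFn(height)` plus
#' Gaussian noise. The returned truth table records the fate and true growth
#' of every tree, conserving counts (`removed + surviving = nTrees`).
#'
#' @param scene a `ForestScene` from [generateScene()].
#' @param scenario a `ChangeScenario` from [changeScenario()].
#' @return A list: `scene2` (the epoch-2 `ForestScene` containing survivors
#'   with grown heights) and `truth` (data.frame `id`, `x`, `y`, `height_1`,
#'   `height_2`, `crown_radius`, `removed`, `height_growth`; growth is 0 for
#'   removed trees).
#' @export
applyChange <- function(scene, scenario) {
  stopifnot(inherits(scene, "ForestScene"), inherits(scenario, "ChangeScenario"))
  tr <- scene$trees
  withr::with_seed(scenario$seed, {
    p <- scenario$removalProbFn(tr$height)
    if (any(p < 0 | p > 1)) stop("removal probabilities outside [0, 1]")
    removed <- runif(nrow(tr)) < p
    growth <- scenario$growthRateFn(tr$height) +
      rnorm(nrow(tr), 0, scenario$growthSd)
    growth[removed] <- 0
    h2 <- pmax(0.5, tr$height + growth)
    r2 <- if (is.null(scenario$radiusGrowthFn)) {
      # keep radii on the generator's allometry as heights grow
      pmax(0.3, tr$crown_radius + 0.15 * (h2 - tr$height))
    } else {
      pmax(0.3, tr$crown_radius + scenario$radiusGrowthFn(tr$height))
    }
    r2[removed] <- tr$crown_radius[removed]
    truth <- data.frame(id = tr$id, x = tr$x, y = tr$y,
                        height_1 = tr$height, height_2 = ifelse(removed, NA, h2),
                        crown_radius = tr$crown_radius, removed = removed,
                        height_growth = ifelse(removed, 0, h2 - tr$height))
    keep <- !removed
    trees2 <- data.frame(id = tr$id[keep], x = tr$x[keep], y = tr$y[keep],
                         height = h2[keep], crown_radius = r2[keep])
    scene2 <- structure(list(trees = trees2, terrain = scene$terrain,
                             extent = scene$extent,
                             crownBaseRatio = scene$crownBaseRatio),
                        class = "ForestScene")
    list(scene2 = scene2, truth = truth)
  })
}

# rasterise the two highest crown envelopes per cell at a working
# resolution; returns integer id matrices for the top and second layer
.crown_id_map <- function(scene, res = 0.25) {
  ext <- scene$extent
  nx <- as.integer(ceiling(ext[1] / res))
  ny <- as.integer(ceiling(ext[2] / res))
  tr <- scene$trees
  top <- matrix(-Inf, nrow = ny, ncol = nx)
  ids <- matrix(0L, nrow = ny, ncol = nx)
  ids2 <- matrix(0L, nrow = ny, ncol = nx)
  if (!nrow(tr)) {
    return(list(ids = ids, ids2 = ids2, res = res, nx = nx, ny = ny))
  }
  cb <- scene$crownBaseRatio
  for (i in seq_len(nrow(tr))) {
    r <- tr$crown_radius[i]
    c0 <- max(1L, as.integer(floor((tr$x[i] - r) / res)) + 1L)
    c1 <- min(nx, as.integer(floor((tr$x[i] + r) / res)) + 1L)
    r0 <- max(1L, as.integer(floor((tr$y[i] - r) / res)) + 1L)
    r1 <- min(ny, as.integer(floor((tr$y[i] + r) / res)) + 1L)
    if (c0 > c1 || r0 > r1) next
    xs <- ((c0:c1) - 0.5) * res
    ys <- ((r0:r1) - 0.5) * res
    d2 <- outer(ys - tr$y[i], xs - tr$x[i], function(a, b) a^2 + b^2)
    inside <- d2 < r^2
    h <- tr$height[i]
    env <- cb * h + (h - cb * h) * sqrt(pmax(0, 1 - d2 / r^2))
    sub_top <- top[r0:r1, c0:c1]
    sub_ids <- ids[r0:r1, c0:c1]
    sub_ids2 <- ids2[r0:r1, c0:c1]
    upd <- inside & env > sub_top
    sub_ids2[upd] <- sub_ids[upd]          # displaced leader becomes layer 2
    low <- inside & env <= sub_top
    sub_ids2[low] <- tr$id[i]              # overtopped crown is layer 2
    sub_top[upd] <- env[upd]
    sub_ids[upd] <- tr$id[i]
    top[r0:r1, c0:c1] <- sub_top
    ids[r0:r1, c0:c1] <- sub_ids
    ids2[r0:r1, c0:c1] <- sub_ids2
  }
  ids2[ids2 == ids] <- 0L
  list(ids = ids, ids2 = ids2, res = res, nx = nx, ny = ny)
}

# envelope elevation of tree rows `row` at point offsets, with footprint
.envelope_z <- function(tr, row, x, y, cbRatio, footprint) {
  d <- sqrt((x - tr$x[row])^2 + (y - tr$y[row])^2)
  d <- pmax(0, d - footprint / 2)
  r <- tr$crown_radius[row]
  h <- tr$height[row]
  cb <- cbRatio * h
  ifelse(d < r, cb + (h - cb) * sqrt(pmax(0, 1 - (d / r)^2)), NA_real_)
}

#' Simulate a lidar acquisition over a scene
#'
#' Samples return positions as a homogeneous Poisson process at the stated
#' density. A return over open ground takes the terrain elevation; a return
#' over a crown takes the crown-envelope elevation (a vertical half-ellipsoid
#' from the crown base to the apex), except that a `groundFraction` share of
#' crown pulses penetrates to the ground. Each return reports the highest
#' envelope point within half a footprint of its nominal position, so larger
#' footprints are more likely to register crown apices. Elevations are
#' perturbed by the vertical noise SD, coordinates by the acquisition's
#' horizontal offset, and scan angles follow from the distance to the nearest
#' flight line.
#'
#' @param scene a `ForestScene`.
#' @param spec an `AcquisitionSpec`.
#' @return data.frame cloud with columns `x`, `y`, `z`, `scan_angle` and an
#'   attribute `"tree_id"` (0 for ground returns) kept for diagnostics.
#' @examples
#' sc <- generateScene(5, extent = c(40, 40), seed = 2)
#' cl <- simulateAcquisition(sc, acquisitionSpec(returnDensity = 4, seed = 3))
#' @export
simulateAcquisition <- function(scene, spec) {
  stopifnot(inherits(scene, "ForestScene"), inherits(spec, "AcquisitionSpec"))
  if (!nrow(scene$trees) && is.null(scene$terrain)) {
    stop("empty scene: nothing to scan", call. = FALSE)
  }
  ext <- scene$extent
  area <- ext[1] * ext[2]
  withr::with_seed(spec$seed, {
    n <- rpois(1, spec$returnDensity * area)
    x <- runif(n, 0, ext[1])
    y <- runif(n, 0, ext[2])

    idmap <- .crown_id_map(scene)
    ci <- pmin(idmap$nx, pmax(1L, as.integer(x / idmap$res) + 1L))
    ri <- pmin(idmap$ny, pmax(1L, as.integer(y / idmap$res) + 1L))
    tid <- idmap$ids[cbind(ri, ci)]

    zg <- scene$terrain(x, y)
    z <- zg
    crown <- which(tid > 0L)
    if (length(crown)) {
      tr <- scene$trees
      # a share of pulses penetrates each crown layer it meets
      pen <- runif(length(crown)) < spec$groundFraction
      hit <- crown[!pen]
      if (length(hit)) {
        row <- match(tid[hit], tr$id)
        env <- .envelope_z(tr, row, x[hit], y[hit], scene$crownBaseRatio,
                           spec$footprintDiameter)
        on <- !is.na(env)
        z[hit[on]] <- zg[hit[on]] + env[on]
        tid[hit[!on]] <- 0L
      }
      # penetrating pulses may return from an overtopped second crown
      through <- crown[pen]
      tid[through] <- 0L
      if (length(through)) {
        tid2 <- idmap$ids2[cbind(ri[through], ci[through])]
        deeper <- runif(length(through)) >= spec$groundFraction
        cand <- which(tid2 > 0L & deeper)
        if (length(cand)) {
          row2 <- match(tid2[cand], tr$id)
          env2 <- .envelope_z(tr, row2, x[through[cand]], y[through[cand]],
                              scene$crownBaseRatio, spec$footprintDiameter)
          on2 <- !is.na(env2)
          sel <- through[cand[on2]]
          z[sel] <- zg[sel] + env2[on2]
          tid[sel] <- tid2[cand[on2]]
        }
      }
    }

    if (spec$verticalNoiseSd > 0) z <- z + rnorm(n, 0, spec$verticalNoiseSd)

    # scan angle from nearest flight line (north-south lines, centred)
    nLines <- max(1L, ceiling(ext[1] / spec$lineSpacing))
    lines_x <- ext[1] / 2 + (seq_len(nLines) - (nLines + 1) / 2) * spec$lineSpacing
    dmat <- outer(x, lines_x, "-")
    nearest <- max.col(-abs(dmat), ties.method = "first")
    dx <- dmat[cbind(seq_len(n), nearest)]
    angle <- atan(dx / spec$altitude) * 180 / pi
    inSwath <- abs(angle) <= spec$maxScanAngle
    cloud <- data.frame(
      x = x[inSwath] + spec$horizontalOffset[1],
      y = y[inSwath] + spec$horizontalOffset[2],
      z = z[inSwath],
      scan_angle = angle[inSwath]
    )
    attr(cloud, "tree_id") <- tid[inSwath]
    cloud
  })
}
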