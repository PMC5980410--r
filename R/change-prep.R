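# ---- scan-angle filter ------------------------------------------------------

#' Filter a point cloud by maximum absolute scan angle
#'
#' Keeps returns with `|scan_angle| <= maxAngle` (boundary inclusive). Wide
#' scan angles see crowns obliquely and occlude one side, so both epochs are
#' filtered to a common angular window before surfaces are built.
#'
#' @param cloud data.frame with a `scan_angle` column, degrees.
#' @param maxAngle maximum absolute scan angle, degrees.
#' @return The filtered cloud.
#' @examples
#' cl <- data.frame(x = 1:6, y = 1:6, z = 0,
#'                  scan_angle = c(-20, -15, 0, 14.9, 15, 16))
#' filterScanAngle(cl)$scan_angle  # -15, 0, 14.9, 15
#' @export
filterScanAngle <- function(cloud, maxAngle = 15) {
  if (!"scan_angle" %in% names(cloud)) {
    stop("cloud has no scan_angle column", call. = FALSE)
  }
  cloud[abs(cloud$scan_angle) <= maxAngle, , drop = FALSE]
}

# ---- density homogenisation -------------------------------------------------

#' Thin the denser of two clouds to a common areal return density
#'
#' Surfaces built by per-cell maxima carry a sampling deficit that shrinks
#' with return density, so two acquisitions of different density yield
#' systematically different canopy heights even over unchanged canopy.
#' Randomly thinning the denser cloud to the sparser cloud's areal density
#' equalises that deficit before any surface is built. Densities are taken
#' as returns over the shared bounding-box area.
#'
#' @param cloud1,cloud2 point clouds (data.frames with `x`, `y`).
#' @param seed integer seed for the random subsample.
#' @return list of the two clouds, the denser one thinned; the applied
#'   keep-fractions are in `attr(, "kept")`.
#' @export
equalizeDensity <- function(cloud1, cloud2, seed = 1L) {
  n1 <- nrow(cloud1); n2 <- nrow(cloud2)
  area <- function(cl) {
    diff(range(cl$x)) * diff(range(cl$y))
  }
  d1 <- n1 / area(cloud1); d2 <- n2 / area(cloud2)
  kept <- c(1, 1)
  withr::with_seed(as.integer(seed), {
    if (d1 > d2) {
      kept[1] <- d2 / d1
      cloud1 <- cloud1[runif(n1) < kept[1], , drop = FALSE]
    } else if (d2 > d1) {
      kept[2] <- d1 / d2
      cloud2 <- cloud2[runif(n2) < kept[2], , drop = FALSE]
    }
  })
  out <- list(cloud1 = cloud1, cloud2 = cloud2)
  attr(out, "kept") <- kept
  out
}

# ---- registration -----------------------------------------------------------

#' Fit an affine co-registration from ground control points
#'
#' Least-squares affine transform mapping source coordinates (second epoch)
#' onto target coordinates (first epoch), minimising the summed squared
#' residuals over the control-point pairs. The reported RMSE is the pooled
#' per-coordinate residual RMS.
#'
#' @param gcps data.frame with columns `src_x`, `src_y`, `dst_x`, `dst_y`
#'   (metres).
#' @return An [AffineTransform-class] with its fit RMSE.
#' @examples
#' g <- data.frame(src_x = runif(50), src_y = runif(50))
#' g$dst_x <- g$src_x + 1.2; g$dst_y <- g$src_y - 0.7
#' fitRegistration(g)
#' @export
fitRegistration <- function(gcps) {
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(gcps))) {
    stop("gcps must have columns src_x, src_y, dst_x, dst_y", call. = FALSE)
  }
  n <- nrow(gcps)
  if (n < 3L) stop("need at least 3 ground control points", call. = FALSE)
  X <- cbind(1, gcps$src_x, gcps$src_y)
  if (qr(X)$rank < 3L) {
    stop("ground control points are collinear; affine fit is degenerate",
         call. = FALSE)
  }
  fx <- stats::.lm.fit(X, gcps$dst_x)
  fy <- stats::.lm.fit(X, gcps$dst_y)
  A <- rbind(c(fx$coefficients[2], fx$coefficients[3]),
             c(fy$coefficients[2], fy$coefficients[3]))
  b <- c(fx$coefficients[1], fy$coefficients[1])
  rmse <- sqrt(mean(c(fx$residuals, fy$residuals)^2))
  affineTransform(A = A, b = b, rmse = rmse)
}

# ---- applying transforms ----------------------------------------------------

#' Apply an affine transform to grids, crown tables or clouds
#'
#' For a point table (crown attributes, cloud, GCPs) the `x`/`y` columns are
#' mapped through the transform. For a [SurfaceGrid-class], the grid is
#' resampled by nearest neighbour onto a reference grid: each reference cell
#' centre is pulled back through the inverse transform and reads the source
#' cell it lands in (nodata where it falls outside).
#'
#' @param x a `SurfaceGrid` or a data.frame with `x`, `y` columns.
#' @param transform an [AffineTransform-class] mapping source to reference
#'   coordinates.
#' @param reference for grids: the [SurfaceGrid-class] defining the output
#'   geometry (defaults to the input's own geometry).
#' @return The transformed object, same class as `x`.
#' @export
setGeneric("applyTransform", function(x, transform, reference = NULL) {
  standardGeneric("applyTransform")
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "data.frame", function(x, transform,
                                                   reference = NULL) {
  stopifnot(is(transform, "AffineTransform"))
  xy <- .transform_xy(transform, x$x, x$y)
  x$x <- xy$x
  x$y <- xy$y
  x
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "SurfaceGrid", function(x, transform,
                                                    reference = NULL) {
  stopifnot(is(transform, "AffineTransform"))
  if (is.null(reference)) reference <- x
  inv <- invertTransform(transform)
  d <- dim(reference@values)
  cc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  ctr <- .cell_centres(reference, cc$row, cc$col)
  src <- .transform_xy(inv, ctr$x, ctr$y)
  idx <- .cell_index(x, src$x, src$y)
  vals <- matrix(NA_real_, d[1], d[2])
  ok <- !is.na(idx$row)
  vals[cbind(cc$row, cc$col)[ok, , drop = FALSE]] <-
    x@values[cbind(idx$row[ok], idx$col[ok])]
  surfaceGrid(vals, origin = reference@origin,
              resolution = reference@resolution, kind = x@kind)
})

# ---- crown matching ---------------------------------------------------------

#' Match crowns between epochs by centroid overlay
#'
#' For each first-epoch crown, the registered second-epoch label raster is
#' read at the crown centroid; a non-background id yields a match. Height,
#' radius and DEM deltas are computed from the two attribute tables, and
#' reciprocal containment records whether the second-epoch centroid falls
#' back inside the first-epoch crown.
#'
#' @param crowns1 epoch-1 crown attribute table ([extractAttributes()]).
#' @param labels2 epoch-2 label [SurfaceGrid-class], already registered onto
#'   the epoch-1 grid.
#' @param crowns2 epoch-2 crown table with centroids already mapped into the
#'   epoch-1 frame.
#' @param labels1 optional epoch-1 label grid, needed for the reciprocal
#'   containment flag.
#' @param dem1,dem2 optional aligned DEMs (epoch 2 registered); when given,
#'   `d_dem` is the absolute DEM difference at the epoch-1 centroid cell.
#' @return data.frame of matches: `id_1`, `id_2`, `height_1`, `height_2`,
#'   `radius_1`, `radius_2`, `d_height`, `d_radius`, `d_dem`, `reciprocal`.
#'   The number of epoch-1 crowns whose centroid fell on background or off
#'   the raster is in `attr(, "n_unmatched")`.
#' @export
matchCrowns <- function(crowns1, labels2, crowns2, labels1 = NULL,
                        dem1 = NULL, dem2 = NULL) {
  stopifnot(is(labels2, "SurfaceGrid"))
  idx <- .cell_index(labels2, crowns1$x, crowns1$y)
  lab2 <- rep(NA_real_, nrow(crowns1))
  ok <- !is.na(idx$row)
  lab2[ok] <- labels2@values[cbind(idx$row[ok], idx$col[ok])]
  hit <- !is.na(lab2) & lab2 > 0
  hitIdx <- which(hit)
  m2 <- match(lab2[hitIdx], crowns2$id)
  keep <- !is.na(m2)
  hitIdx <- hitIdx[keep]; m2 <- m2[keep]

  dDem <- rep(NA_real_, length(hitIdx))
  if (!is.null(dem1) && !is.null(dem2)) {
    if (!gridsAligned(dem1, dem2)) .stop_misaligned("matchCrowns (DEMs)")
    di <- .cell_index(dem1, crowns1$x[hitIdx], crowns1$y[hitIdx])
    okd <- !is.na(di$row)
    dDem[okd] <- abs(dem1@values[cbind(di$row[okd], di$col[okd])] -
                     dem2@values[cbind(di$row[okd], di$col[okd])])
  }

  recip <- rep(NA, length(hitIdx))
  if (!is.null(labels1)) {
    stopifnot(is(labels1, "SurfaceGrid"))
    ri <- .cell_index(labels1, crowns2$x[m2], crowns2$y[m2])
    okr <- !is.na(ri$row)
    back <- rep(NA_real_, length(hitIdx))
    back[okr] <- labels1@values[cbind(ri$row[okr], ri$col[okr])]
    recip <- !is.na(back) & back == crowns1$id[hitIdx]
  }

  out <- data.frame(
    id_1 = crowns1$id[hitIdx],
    id_2 = crowns2$id[m2],
    height_1 = crowns1$height[hitIdx],
    height_2 = crowns2$height[m2],
    radius_1 = crowns1$radius[hitIdx],
    radius_2 = crowns2$radius[m2],
    d_height = crowns2$height[m2] - crowns1$height[hitIdx],
    d_radius = crowns2$radius[m2] - crowns1$radius[hitIdx],
    d_dem = dDem,
    reciprocal = recip
  )
  attr(out, "n_unmatched") <- nrow(crowns1) - nrow(out)
  out
}

# ---- growth filters ---------------------------------------------------------

#' Apply the four growth-analysis quality filters
#'
#' Retains matches that (1) show reciprocal centroid containment, (2) have
#' less than `maxDHeight` metres of absolute height change, (3) have less
#' than `maxDDem` metres of underlying DEM difference, and (4) have less
#' than `maxRadiusChange` (fractional) change in crown radius. All four
#' thresholds are strict inequalities; a match exactly at a threshold is
#' excluded. Filters whose inputs are missing (`NA` deltas) are skipped for
#' that match and reported.
#'
#' @param matches match table from [matchCrowns()].
#' @param maxDHeight height-change threshold, metres.
#' @param maxDDem DEM-difference threshold, metres.
#' @param maxRadiusChange fractional crown-radius change threshold.
#' @param requireReciprocal if `FALSE`, filter 1 reduces to the one-way
#'   containment already implied by the centroid overlay.
#' @return list: `matches` (retained rows, plus logical `pass_*` columns on
#'   the full input in `flags`), `counts` (per-filter marginal exclusions,
#'   first-failing exclusions, `n_in`, `n_retained`).
#' @export
applyGrowthFilters <- function(matches, maxDHeight = 5, maxDDem = 1,
                               maxRadiusChange = 1.0,
                               requireReciprocal = TRUE) {
  p1 <- if (requireReciprocal) {
    !is.na(matches$reciprocal) & matches$reciprocal
  } else rep(TRUE, nrow(matches))
  p2 <- abs(matches$d_height) < maxDHeight
  p3 <- ifelse(is.na(matches$d_dem), TRUE, matches$d_dem < maxDDem)
  p4 <- abs(matches$d_radius) / matches$radius_1 < maxRadiusChange
  pass <- p1 & p2 & p3 & p4
  flags <- cbind(matches,
                 pass_containment = p1, pass_height = p2,
                 pass_dem = p3, pass_radius = p4, pass_all = pass)
  firstFail <- rep(NA_character_, nrow(matches))
  firstFail[!p4] <- "radius"
  firstFail[!p3] <- "dem"
  firstFail[!p2] <- "height"
  firstFail[!p1] <- "containment"
  counts <- list(
    n_in = nrow(matches),
    n_retained = sum(pass),
    marginal = c(containment = sum(!p1), height = sum(!p2),
                 dem = sum(!p3), radius = sum(!p4)),
    first_failing = table(factor(firstFail,
                                 levels = c("containment", "height",
                                            "dem", "radius")))
  )
  list(matches = matches[pass, , drop = FALSE], flags = flags,
       counts = counts)
}

#' Sweep the growth-filter thresholds
#'
#' Re-applies [applyGrowthFilters()] over a grid of threshold combinations
#' and records the retained sample size and the median height change per
#' height class, to show how stable the growth curve is under filter choice.
#'
#' @param matches match table from [matchCrowns()].
#' @param thresholds data.frame of combinations with columns `maxDHeight`,
#'   `maxDDem`, `maxRadiusChange` (e.g. from [expand.grid()]).
#' @param binWidth height-class width for the growth summary, metres.
#' @param minN minimum class size.
#' @return list: `combos` (the thresholds with retained `n`), `medians`
#'   (long data.frame: combo index, class midpoint, class `n`, median
#'   height change).
#' @export
filterSensitivitySweep <- function(matches, thresholds, binWidth = 5,
                                   minN = 20L) {
  if (!nrow(thresholds)) stop("empty threshold grid", call. = FALSE)
  need <- c("maxDHeight", "maxDDem", "maxRadiusChange")
  if (!all(need %in% names(thresholds))) {
    stop("thresholds must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  combos <- as.data.frame(thresholds)
  combos$n <- NA_integer_
  med <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    f <- applyGrowthFilters(matches,
                            maxDHeight = combos$maxDHeight[i],
                            maxDDem = combos$maxDDem[i],
                            maxRadiusChange = combos$maxRadiusChange[i])
    combos$n[i] <- nrow(f$matches)
    if (nrow(f$matches)) {
      s <- binByHeight(f$matches$height_1, f$matches$d_height,
                       binWidth = binWidth, minN = minN)
      if (nrow(s)) {
        med[[i]] <- data.frame(combo = i, mid = (s$binLower + s$binUpper) / 2,
                               n = s$n, median = s$median)
      }
    }
  }
  list(combos = combos, medians = do.call(rbind, med))
}
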