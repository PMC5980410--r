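# ---- internal: grid geometry helpers ---------------------------------------

# snap a bounding box to a resolution; returns list(origin, nrow, ncol)
.grid_from_extent <- function(xmin, xmax, ymin, ymax, resolution) {
  x0 <- floor(xmin / resolution) * resolution
  y0 <- floor(ymin / resolution) * resolution
  nc <- max(1L, as.integer(ceiling((xmax - x0) / resolution)))
  nr <- max(1L, as.integer(ceiling((ymax - y0) / resolution)))
  list(origin = c(x0, y0), nrow = nr, ncol = nc)
}

# NA-aware separable Gaussian smoothing by normalised convolution.
# Nodata cells stay nodata; valid cells average over valid neighbours with
# renormalised weights. A kernel truncated at 3 sigma is used.
.gaussian_smooth <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  k <- max(1L, as.integer(ceiling(3 * sigma_cells)))
  kern <- exp(-((-k:k)^2) / (2 * sigma_cells^2))
  kern <- kern / sum(kern)
  nr <- nrow(m); nc <- ncol(m)
  valid <- is.finite(m)
  v <- ifelse(valid, m, 0)
  w <- ifelse(valid, 1, 0)
  pad <- function(x) {
    out <- matrix(0, nr + 2L * k, nc + 2L * k)
    out[(k + 1):(k + nr), (k + 1):(k + nc)] <- x
    out
  }
  conv1 <- function(x) { # along rows (i.e. down each column)
    res <- stats::filter(x, kern, method = "convolution", sides = 2)
    matrix(res, nrow = nrow(x))
  }
  vs <- pad(v); ws <- pad(w)
  vs <- conv1(vs); ws <- conv1(ws)
  vs <- t(conv1(t(vs))); ws <- t(conv1(t(ws)))
  vs <- vs[(k + 1):(k + nr), (k + 1):(k + nc)]
  ws <- ws[(k + 1):(k + nr), (k + 1):(k + nc)]
  out <- matrix(NA_real_, nr, nc)
  ok <- valid & ws > 1e-12
  out[ok] <- vs[ok] / ws[ok]
  out
}

# bilinear interpolation on a coarse cell-centre grid with edge clamping
.bilinear <- function(vals, origin, res, x, y) {
  nr <- nrow(vals); nc <- ncol(vals)
  gx <- (x - origin[1]) / res - 0.5
  gy <- (y - origin[2]) / res - 0.5
  cx <- pmin(pmax(gx, 0), nc - 1)
  cy <- pmin(pmax(gy, 0), nr - 1)
  c0 <- pmin(nc - 1L, pmax(1L, floor(cx) + 1L)); c1 <- c0 + 1L
  r0 <- pmin(nr - 1L, pmax(1L, floor(cy) + 1L)); r1 <- r0 + 1L
  if (nc == 1L) { c0 <- c1 <- 1L }
  if (nr == 1L) { r0 <- r1 <- 1L }
  fx <- pmin(pmax(cx - (c0 - 1L), 0), 1)
  fy <- pmin(pmax(cy - (r0 - 1L), 0), 1)
  v00 <- vals[cbind(r0, c0)]; v01 <- vals[cbind(r0, c1)]
  v10 <- vals[cbind(r1, c0)]; v11 <- vals[cbind(r1, c1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# fill NA cells of a matrix by repeated 3x3 neighbour means
.fill_na_neighbours <- function(m, max_iter = 64L) {
  for (it in seq_len(max_iter)) {
    na <- which(is.na(m))
    if (!length(na)) break
    sm <- .gaussian_smooth_box(m)
    m[na] <- sm[na]
  }
  m
}

.gaussian_smooth_box <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    src <- m[rs, cs, drop = FALSE]
    ok <- is.finite(src)
    src[!ok] <- 0
    acc[rt, ct] <- acc[rt, ct] + src
    cnt[rt, ct] <- cnt[rt, ct] + ok
  }
  out <- matrix(NA_real_, nr, nc)
  pos <- cnt > 0
  out[pos] <- acc[pos] / cnt[pos]
  out
}

# ---- ground classification --------------------------------------------------

#' Classify ground returns in a point cloud
#'
#' A two-step morphological minimum filter: the minimum elevation is taken
#' per coarse cell, a provisional minimum surface is interpolated bilinearly
#' between coarse cell centres, and all returns within `tol` metres above
#' that surface (or below it) are labelled ground.
#'
#' @param cloud data.frame with `x`, `y`, `z`.
#' @param coarseRes coarse cell size for the minimum filter, metres.
#' @param tol vertical inclusion tolerance above the minimum surface, metres.
#' @return The subset of `cloud` rows classified as ground.
#' @export
classifyGround <- function(cloud, coarseRes = 5, tol = 0.3) {
  if (!nrow(cloud)) stop("empty cloud", call. = FALSE)
  dt <- as.data.table(cloud)
  g <- .grid_from_extent(min(dt$x), max(dt$x), min(dt$y), max(dt$y), coarseRes)
  ci <- pmin(g$ncol, pmax(1L, as.integer(floor((dt$x - g$origin[1]) / coarseRes)) + 1L))
  ri <- pmin(g$nrow, pmax(1L, as.integer(floor((dt$y - g$origin[2]) / coarseRes)) + 1L))
  dt[, `:=`(row_ = ri, col_ = ci)]
  mins <- dt[, .(zmin = min(z)), by = .(row_, col_)]
  if (nrow(mins) < 3L) {
    stop("fewer than 3 coarse cells contain points; cannot classify ground",
         call. = FALSE)
  }
  minGrid <- matrix(NA_real_, g$nrow, g$ncol)
  minGrid[cbind(mins$row_, mins$col_)] <- mins$zmin
  minGrid <- .fill_na_neighbours(minGrid)
  surf <- .bilinear(minGrid, g$origin, coarseRes, dt$x, dt$y)
  ground <- dt$z <= surf + tol
  as.data.frame(dt[ground, .(x, y, z,
                             scan_angle = if ("scan_angle" %in% names(dt))
                               scan_angle else NA_real_)])
}

# ---- DEM --------------------------------------------------------------------

#' Build a digital elevation model from ground returns
#'
#' Interpolates classified ground returns onto a regular grid by tiled local
#' least-squares planes: the scene is divided into `tileSize`-metre tiles,
#' each tile's plane is fitted to the ground points within the tile expanded
#' by half a tile on all sides, and evaluated at cell centres. Tiles with
#' too few or degenerate (collinear) points fall back to the global plane.
#' On exactly planar input the result is exact. Cells outside the convex
#' hull of the ground points are nodata.
#'
#' @param ground data.frame of ground returns (`x`, `y`, `z`).
#' @param resolution output cell size, metres.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; defaults to the point
#'   bounding box snapped to the resolution.
#' @param tileSize local-fit tile size, metres.
#' @return A [SurfaceGrid-class] of kind `"DEM"`.
#' @export
buildDEM <- function(ground, resolution = 0.5, extent = NULL, tileSize = 10) {
  if (nrow(ground) < 3L) stop("need at least 3 ground points", call. = FALSE)
  X <- cbind(1, ground$x, ground$y)
  if (qr(X)$rank < 3L) {
    stop("degenerate ground geometry: points are collinear", call. = FALSE)
  }
  if (is.null(extent)) {
    extent <- c(min(ground$x), max(ground$x), min(ground$y), max(ground$y))
  }
  g <- .grid_from_extent(extent[1], extent[2], extent[3], extent[4], resolution)
  globalFit <- stats::.lm.fit(X, ground$z)$coefficients

  vals <- matrix(NA_real_, g$nrow, g$ncol)
  ntx <- max(1L, ceiling((g$ncol * resolution) / tileSize))
  nty <- max(1L, ceiling((g$nrow * resolution) / tileSize))
  gx <- ground$x; gy <- ground$y; gz <- ground$z
  for (ty in seq_len(nty)) {
    y0 <- g$origin[2] + (ty - 1) * tileSize
    y1 <- y0 + tileSize
    rsel <- which(gy >= y0 - tileSize / 2 & gy < y1 + tileSize / 2)
    r0 <- as.integer((ty - 1) * tileSize / resolution) + 1L
    r1 <- min(g$nrow, as.integer(ty * tileSize / resolution))
    if (r0 > r1) next
    for (tx in seq_len(ntx)) {
      x0 <- g$origin[1] + (tx - 1) * tileSize
      x1 <- x0 + tileSize
      sel <- rsel[gx[rsel] >= x0 - tileSize / 2 & gx[rsel] < x1 + tileSize / 2]
      c0 <- as.integer((tx - 1) * tileSize / resolution) + 1L
      c1 <- min(g$ncol, as.integer(tx * tileSize / resolution))
      if (c0 > c1) next
      cf <- globalFit
      if (length(sel) >= 3L) {
        Xi <- cbind(1, gx[sel], gy[sel])
        fit <- tryCatch(stats::.lm.fit(Xi, gz[sel]), error = function(e) NULL)
        if (!is.null(fit) && qr(Xi)$rank == 3L) cf <- fit$coefficients
      }
      xs <- g$origin[1] + ((c0:c1) - 0.5) * resolution
      ys <- g$origin[2] + ((r0:r1) - 0.5) * resolution
      vals[r0:r1, c0:c1] <- outer(ys * cf[3], xs * cf[2], "+") + cf[1]
    }
  }

  # nodata outside the convex hull of the ground points
  hull <- grDevices::chull(gx, gy)
  hx <- gx[hull]; hy <- gy[hull]
  cc <- expand.grid(row = seq_len(g$nrow), col = seq_len(g$ncol))
  ctr <- list(x = g$origin[1] + (cc$col - 0.5) * resolution,
              y = g$origin[2] + (cc$row - 0.5) * resolution)
  inside <- .point_in_polygon(ctr$x, ctr$y, hx, hy)
  vals[cbind(cc$row, cc$col)[!inside, , drop = FALSE]] <- NA_real_
  surfaceGrid(vals, origin = g$origin, resolution = resolution, kind = "DEM")
}

# even-odd crossing test, vectorised over query points; boundary-tolerant
.point_in_polygon <- function(x, y, px, py, eps = 1e-9) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi + eps)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# ---- CHM --------------------------------------------------------------------

#' Build a smoothed canopy height model
#'
#' Per cell of the DEM grid, the maximum return elevation minus the DEM
#' (negatives clamped to zero). Each return is treated as a small disk of
#' radius `splatRadius` rather than a dimensionless point, so it can set the
#' maximum of every cell its footprint touches; this stabilises the maximum
#' surface when acquisitions differ in return density, which would otherwise
#' bias height change estimates. Canopy cells with no returns are pit-filled
#' with the median of their valid 3x3 neighbours (else 0), then the surface
#' is smoothed with an NA-aware Gaussian kernel of SD `smoothingSigma`
#' metres. Cells where the DEM is nodata stay nodata.
#'
#' @param cloud data.frame with `x`, `y`, `z`.
#' @param dem a [SurfaceGrid-class] of kind `"DEM"` defining the target grid.
#' @param resolution must equal the DEM resolution (no implicit resampling).
#' @param smoothingSigma Gaussian smoothing SD in metres; 0 disables
#'   smoothing.
#' @param splatRadius radius of the disk each return occupies, metres; 0
#'   reduces to point-in-cell rasterisation. Values up to half the cell size
#'   are supported.
#' @return A [SurfaceGrid-class] of kind `"CHM"`.
#' @export
buildCHM <- function(cloud, dem, resolution = gridResolution(dem),
                     smoothingSigma = 0.5, splatRadius = 0.25) {
  stopifnot(is(dem, "SurfaceGrid"), splatRadius >= 0)
  if (abs(resolution - dem@resolution) > 1e-12) {
    .stop_misaligned("buildCHM")
  }
  splatRadius <- min(splatRadius, resolution / 2)
  nr <- nrow(dem@values); nc <- ncol(dem@values)
  dt <- as.data.table(cloud)
  s <- splatRadius
  shifts <- if (s > 0) {
    # each return's disk touches at most 4 cells for s <= half the cell size;
    # probing the 9 shifted positions covers them all
    list(c(0, 0), c(s, 0), c(-s, 0), c(0, s), c(0, -s),
         c(s, s), c(s, -s), c(-s, s), c(-s, -s))
  } else {
    list(c(0, 0))
  }
  mx <- rbindlist(lapply(shifts, function(d) {
    idx <- .cell_index(dem, dt$x + d[1], dt$y + d[2])
    keep <- !is.na(idx$row)
    data.table(row_ = idx$row[keep], col_ = idx$col[keep],
               z = dt$z[keep])[, .(zmax = max(z)), by = .(row_, col_)]
  }))[, .(zmax = max(zmax)), by = .(row_, col_)]

  hag <- matrix(NA_real_, nr, nc)
  hag[cbind(mx$row_, mx$col_)] <- mx$zmax
  hag <- hag - dem@values
  hag[hag < 0] <- 0

  # pit fill: cells with a valid DEM but no returns take the median of their
  # valid 3x3 neighbours, else 0
  demOk <- is.finite(dem@values)
  empty <- which(demOk & !is.finite(hag))
  if (length(empty)) {
    er <- ((empty - 1L) %% nr) + 1L
    ec <- ((empty - 1L) %/% nr) + 1L
    nb <- matrix(NA_real_, length(empty), 8L)
    k <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      k <- k + 1L
      rr <- er + dr; ccn <- ec + dc
      ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
      nb[ok, k] <- hag[cbind(rr[ok], ccn[ok])]
    }
    med <- apply(nb, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) median(v) else 0
    })
    hag[empty] <- med
  }
  hag[!demOk] <- NA_real_

  if (smoothingSigma > 0) {
    hag <- .gaussian_smooth(hag, smoothingSigma / dem@resolution)
    hag[hag < 0] <- 0
  }
  surfaceGrid(hag, origin = dem@origin, resolution = dem@resolution,
              kind = "CHM")
}

# ---- differencing -----------------------------------------------------------

#' Difference two canopy height models
#'
#' Computes `chm1 - chm2` (positive where canopy present in the first epoch
#' is gone in the second). Grids must be aligned; nodata in either input
#' propagates to the output.
#'
#' @param chm1,chm2 aligned [SurfaceGrid-class] CHMs (epoch 1, epoch 2).
#' @return A [SurfaceGrid-class] of kind `"DIFF"`.
#' @export
differenceCHM <- function(chm1, chm2) {
  stopifnot(is(chm1, "SurfaceGrid"), is(chm2, "SurfaceGrid"))
  if (!gridsAligned(chm1, chm2)) .stop_misaligned("differenceCHM")
  surfaceGrid(chm1@values - chm2@values, origin = chm1@origin,
              resolution = chm1@resolution, kind = "DIFF")
}
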