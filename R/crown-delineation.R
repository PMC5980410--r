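# ---- markers ----------------------------------------------------------------

# local maxima of a grid above minHeight within a (2w+1)^2 neighbourhood,
# with adjacent (plateau) candidates merged into one marker per component.
# Returns an integer matrix: 0 everywhere except candidate cells, which carry
# their marker id. Ids are numbered by the component's smallest column-major
# linear index, so runs are reproducible.
.find_markers <- function(values, minHeight, windowRadius = 1L) {
  finite <- is.finite(values)
  v <- ifelse(finite, values, -Inf)
  dil <- v
  for (i in seq_len(windowRadius)) dil <- .dilate3x3(dil)
  cand <- finite & values >= minHeight & values == dil
  if (!any(cand)) return(matrix(0L, nrow(values), ncol(values)))
  comp <- cpp_label_components(cand)
  comp
}

.dilate3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    out[rt, ct] <- pmax(out[rt, ct], m[rs, cs, drop = FALSE])
  }
  out
}

# ---- watershed --------------------------------------------------------------

#' Marker-controlled watershed segmentation of a canopy height model
#'
#' Markers are the local maxima of the (already smoothed) CHM at or above
#' `minTreeHeight` within a `(2*windowRadius+1)` square neighbourhood;
#' adjacent equal-valued maxima merge into one marker. Every canopy cell
#' (CHM >= `minTreeHeight`) is assigned to exactly one marker by following
#' the path of steepest ascent (8-neighbourhood; ties broken by scan order,
#' so runs are reproducible). Cells below the threshold are background (0).
#' With `windowRadius > 1`, catchments of suppressed maxima are merged into
#' the marker nearest their summit.
#'
#' @param chm a [SurfaceGrid-class] CHM (or DIFF surface).
#' @param minTreeHeight minimum height for canopy cells and markers, metres.
#' @param windowRadius marker neighbourhood radius in cells.
#' @return A [SurfaceGrid-class] of kind `"LABELS"` whose integer values are
#'   crown ids (0 = background).
#' @examples
#' xy <- expand.grid(r = 1:30, c = 1:30)
#' v <- matrix(8 * exp(-((xy$r - 10)^2 + (xy$c - 10)^2) / 18) +
#'             10 * exp(-((xy$r - 22)^2 + (xy$c - 22)^2) / 18), 30, 30)
#' labs <- watershedSegment(surfaceGrid(v, c(0, 0), 1, "CHM"),
#'                          minTreeHeight = 2)
#' max(gridValues(labs))  # two crowns
#' @export
watershedSegment <- function(chm, minTreeHeight = 2, windowRadius = 1L) {
  stopifnot(is(chm, "SurfaceGrid"))
  v <- chm@values
  mask <- is.finite(v) & v >= minTreeHeight
  out <- matrix(0, nrow(v), ncol(v))
  if (!any(mask)) {
    return(surfaceGrid(out, origin = chm@origin, resolution = chm@resolution,
                       kind = "LABELS"))
  }
  markers <- .find_markers(v, minTreeHeight, windowRadius)
  vv <- ifelse(is.finite(v), v, -Inf)
  res <- cpp_steepest_labels(vv, mask, markers)
  lab <- res$labels
  if (any(lab[mask] == 0L)) {
    # catchments of window-suppressed maxima: attach to the nearest marker
    term <- res$terminal
    un <- which(mask & lab == 0L)
    tix <- unique(term[un])
    mcells <- which(markers > 0L)
    nr <- nrow(v)
    mr <- ((mcells - 1L) %% nr) + 1L
    mc <- ((mcells - 1L) %/% nr) + 1L
    for (t in tix) {
      tr <- ((t - 1L) %% nr) + 1L
      tc <- ((t - 1L) %/% nr) + 1L
      d2 <- (mr - tr)^2 + (mc - tc)^2
      lab[term == t & mask] <- markers[mcells[which.min(d2)]]
    }
  }
  surfaceGrid(lab + 0, origin = chm@origin, resolution = chm@resolution,
              kind = "LABELS")
}

# ---- attributes -------------------------------------------------------------

#' Extract crown attributes from a label grid
#'
#' Per crown id: area from the cell count, circle-equivalent radius
#' `sqrt(area/pi)`, centroid as the mean of cell centres, and height as the
#' maximum smoothed-CHM value within the crown.
#'
#' @param labels a [SurfaceGrid-class] of kind `"LABELS"`.
#' @param chm the aligned [SurfaceGrid-class] the labels were derived from.
#' @param layer integer canopy layer tag (0 = overstory).
#' @return data.frame with columns `id`, `layer`, `x`, `y`, `area`, `radius`,
#'   `height` (metres and square metres).
#' @export
extractAttributes <- function(labels, chm, layer = 0L) {
  stopifnot(is(labels, "SurfaceGrid"), is(chm, "SurfaceGrid"))
  if (!gridsAligned(labels, chm)) .stop_misaligned("extractAttributes")
  lv <- labels@values
  sel <- which(is.finite(lv) & lv > 0)
  if (!length(sel)) {
    return(data.frame(id = integer(), layer = integer(), x = numeric(),
                      y = numeric(), area = numeric(), radius = numeric(),
                      height = numeric()))
  }
  nr <- nrow(lv)
  res <- labels@resolution
  dt <- data.table(
    label = as.integer(lv[sel]),
    row_ = ((sel - 1L) %% nr) + 1L,
    col_ = ((sel - 1L) %/% nr) + 1L,
    z = chm@values[sel]
  )
  ag <- dt[, .(
    n = .N,
    x = labels@origin[1] + (mean(col_) - 0.5) * res,
    y = labels@origin[2] + (mean(row_) - 0.5) * res,
    height = max(z, na.rm = TRUE)
  ), by = label]
  setorder(ag, label)
  data.frame(id = ag$label, layer = as.integer(layer), x = ag$x, y = ag$y,
             area = ag$n * res^2, radius = sqrt(ag$n * res^2 / pi),
             height = ag$height)
}

# ---- vertical stratification ------------------------------------------------

#' Split in-segment returns into overstory and understory
#'
#' Builds a histogram of above-ground return heights inside one crown
#' segment (ground hits below `groundCut` excluded) and looks for the
#' largest empty vertical gap whose top lies below `gapCeilingFraction`
#' of the segment's maximum height. If that gap spans at least `minGap`
#' metres and at least `minFraction` of the returns lie below it, the
#' segment hosts a distinct understory layer and is split at the gap
#' midpoint.
#'
#' @param heights numeric vector of above-ground return heights in the
#'   segment, metres.
#' @param binWidth histogram bin width, metres.
#' @param minGap minimum empty gap to declare a split, metres.
#' @param minFraction minimum fraction of returns below the gap.
#' @param minPoints minimum usable returns; below this no split is reported.
#' @param groundCut returns below this height are treated as ground hits and
#'   ignored, metres.
#' @param gapCeilingFraction gaps must end below this fraction of the
#'   segment maximum.
#' @return list with `split` (flag), `splitHeight` (metres, `NA` when not
#'   split), and `understory` (logical index into `heights`, all `FALSE`
#'   when not split).
#' @export
classifyLayers <- function(heights, binWidth = 0.5, minGap = 2,
                           minFraction = 0.1, minPoints = 10L,
                           groundCut = 1, gapCeilingFraction = 0.7) {
  no <- list(split = FALSE, splitHeight = NA_real_,
             understory = rep(FALSE, length(heights)))
  use <- heights >= groundCut
  h <- heights[use]
  if (length(h) < minPoints) return(no)
  segMax <- max(h)
  if (segMax <= groundCut + minGap) return(no)
  breaks <- seq(0, segMax + binWidth, by = binWidth)
  cnt <- tabulate(pmin(length(breaks) - 1L, findInterval(h, breaks)),
                  nbins = length(breaks) - 1L)
  emptyRuns <- rle(cnt == 0)
  ends <- cumsum(emptyRuns$lengths)
  starts <- ends - emptyRuns$lengths + 1L
  best <- NULL
  for (i in which(emptyRuns$values)) {
    gapBottom <- breaks[starts[i]]
    gapTop <- breaks[ends[i] + 1L]
    if (gapBottom < groundCut) next               # the below-ground-cut void
    if (gapTop > gapCeilingFraction * segMax) next
    span <- gapTop - gapBottom
    if (span < minGap) next
    fracBelow <- mean(h < gapBottom)
    if (fracBelow < minFraction) next
    if (is.null(best) || span > best$span) {
      best <- list(span = span, mid = (gapBottom + gapTop) / 2)
    }
  }
  if (is.null(best)) return(no)
  list(split = TRUE, splitHeight = best$mid,
       understory = heights < best$mid & heights >= 0)
}

# ---- multistory delineation -------------------------------------------------

#' Iterative multistory crown delineation
#'
#' Layer 0 is the watershed segmentation of the smoothed CHM. Each segment's
#' returns are then stratified vertically ([classifyLayers()]); where a
#' distinct understory is found, the understory returns of all splitting
#' segments are rasterised into a secondary CHM, smoothed and segmented
#' again, producing the next canopy layer. Iteration stops when no segment
#' splits or after `maxLayers` layers. Crown ids are unique across layers
#' within the call.
#'
#' @param chm smoothed [SurfaceGrid-class] CHM.
#' @param cloud point cloud data.frame (`x`, `y`, `z`).
#' @param dem aligned [SurfaceGrid-class] DEM (for above-ground heights).
#' @param minTreeHeight minimum tree height, metres.
#' @param smoothingSigma Gaussian smoothing for secondary CHMs, metres.
#' @param maxLayers maximum number of canopy layers.
#' @param windowRadius marker neighbourhood radius (cells).
#' @param ... further arguments passed to [classifyLayers()].
#' @return list with `crowns` (attribute data.frame over all layers),
#'   `labels` (list of label [SurfaceGrid-class]s, one per layer) and
#'   `nLayers`.
#' @export
delineateMultistory <- function(chm, cloud, dem, minTreeHeight = 2,
                                smoothingSigma = 0.5, maxLayers = 4L,
                                windowRadius = 1L, ...) {
  stopifnot(is(chm, "SurfaceGrid"), is(dem, "SurfaceGrid"))
  if (!gridsAligned(chm, dem)) .stop_misaligned("delineateMultistory")
  labs0 <- watershedSegment(chm, minTreeHeight, windowRadius)
  crowns <- extractAttributes(labs0, chm, layer = 0L)
  labelsList <- list(labs0)

  # above-ground heights + cell index per point
  dt <- as.data.table(cloud)
  idx <- .cell_index(chm, dt$x, dt$y)
  keep <- !is.na(idx$row)
  dt <- dt[keep]
  dt[, `:=`(row_ = idx$row[keep], col_ = idx$col[keep])]
  dt[, hag := z - dem@values[cbind(row_, col_)]]
  dt <- dt[is.finite(hag)]

  currentLabs <- labs0
  idOffset <- if (nrow(crowns)) max(crowns$id) else 0L
  layer <- 0L
  activeIdx <- seq_len(nrow(dt))

  while (layer < maxLayers - 1L) {
    lv <- currentLabs@values
    sub <- dt[activeIdx]
    sub[, orig := activeIdx]
    sub[, label := as.integer(lv[cbind(row_, col_)])]
    sub <- sub[!is.na(label) & label > 0L]
    if (!nrow(sub)) break
    splitBy <- sub[, {
      cl <- classifyLayers(hag, ...)
      if (cl$split) .(keeprow = .I[cl$understory]) else .(keeprow = integer(0))
    }, by = label]
    underRows <- splitBy$keeprow
    if (!length(underRows)) break

    und <- sub[underRows]
    uv <- matrix(NA_real_, nrow(lv), ncol(lv))
    mx <- und[, .(zmax = max(hag)), by = .(row_, col_)]
    uv[cbind(mx$row_, mx$col_)] <- pmax(0, mx$zmax)
    if (smoothingSigma > 0) {
      uv <- .gaussian_smooth(uv, smoothingSigma / chm@resolution)
    }
    uchm <- surfaceGrid(pmax(uv, 0), origin = chm@origin,
                        resolution = chm@resolution, kind = "CHM")
    ulabs <- watershedSegment(uchm, minTreeHeight, windowRadius)
    uc <- extractAttributes(ulabs, uchm, layer = layer + 1L)
    if (!nrow(uc)) break
    uc$id <- uc$id + idOffset
    relabelled <- ulabs@values
    relabelled[relabelled > 0] <- relabelled[relabelled > 0] + idOffset
    ulabs <- surfaceGrid(relabelled, origin = chm@origin,
                         resolution = chm@resolution, kind = "LABELS")
    crowns <- rbind(crowns, uc)
    labelsList[[length(labelsList) + 1L]] <- ulabs
    idOffset <- max(uc$id)

    # next iteration works on the understory returns only
    activeIdx <- und$orig
    currentLabs <- ulabs
    layer <- layer + 1L
  }
  list(crowns = crowns, labels = labelsList, nLayers = layer + 1L)
}
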