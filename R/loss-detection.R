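# ---- difference segmentation ------------------------------------------------

#' Segment the CHM difference surface into candidate loss crowns
#'
#' Cells whose height loss (epoch-1 CHM minus epoch-2 CHM) is at least
#' `minLossHeight` are candidate loss canopy; the same marker-controlled
#' watershed used for crown delineation segments them, and attributes
#' (height = maximum difference, area, circle-equivalent radius, centroid)
#' are extracted per segment. Growth-only scenes (difference never reaching
#' the threshold) yield an empty segmentation, not an error.
#'
#' @param diff [SurfaceGrid-class] of kind `"DIFF"` from [differenceCHM()].
#' @param minLossHeight candidate threshold, metres; also the watershed
#'   background cut.
#' @param windowRadius marker neighbourhood radius, cells.
#' @return list: `labels` (label [SurfaceGrid-class]), `segments`
#'   (attribute data.frame as in [extractAttributes()]).
#' @export
segmentDifference <- function(diff, minLossHeight = 3, windowRadius = 1L) {
  stopifnot(is(diff, "SurfaceGrid"))
  labels <- watershedSegment(diff, minTreeHeight = minLossHeight,
                             windowRadius = windowRadius)
  segments <- extractAttributes(labels, diff, layer = 0L)
  list(labels = labels, segments = segments, minLossHeight = minLossHeight)
}

# ---- loss matching ----------------------------------------------------------

#' Match difference segments to first-epoch crowns to flag tree losses
#'
#' Each difference segment is paired with the first-epoch crown it overlaps
#' most (cell count on the shared grid; ties broken by smaller height delta,
#' then lower crown id). The pair is a loss event iff the segment and crown
#' differ by less than `heightTol` metres in height and less than `areaTol`
#' (fractional) in crown area — both strict inequalities, which discards the
#' small edge slivers that arise when the second acquisition under-resolves
#' crown borders. Each first-epoch crown is used at most once; competing
#' segments are resolved by smaller height delta, then lower segment id.
#'
#' The two areas are compared on a common height support: the difference
#' layer only contains cells at or above its candidate threshold, so when
#' `chm1` is supplied the crown area is likewise counted over crown cells at
#' or above that threshold. Without `chm1` the full delineated crown area is
#' used, which systematically under-matches short crowns.
#'
#' @param diffSeg result of [segmentDifference()].
#' @param crowns1 epoch-1 crown table.
#' @param labels1 epoch-1 label [SurfaceGrid-class] (aligned with the
#'   difference grid).
#' @param chm1 optional epoch-1 [SurfaceGrid-class] CHM for the
#'   common-support area (recommended).
#' @param heightTol height agreement tolerance, metres.
#' @param areaTol fractional area agreement tolerance.
#' @return data.frame of loss events: `id_1`, `diff_segment_id`,
#'   `height_delta_match`, `area_ratio_delta`, `height_1`.
#' @export
matchLoss <- function(diffSeg, crowns1, labels1, chm1 = NULL, heightTol = 3,
                      areaTol = 0.30) {
  stopifnot(is(labels1, "SurfaceGrid"))
  dl <- diffSeg$labels
  if (!gridsAligned(dl, labels1)) .stop_misaligned("matchLoss")
  segs <- diffSeg$segments
  empty <- data.frame(id_1 = integer(), diff_segment_id = integer(),
                      height_delta_match = numeric(),
                      area_ratio_delta = numeric(), height_1 = numeric())
  if (!nrow(segs)) return(empty)

  # crown areas on the difference layer's height support
  crownArea <- crowns1$area
  if (!is.null(chm1)) {
    stopifnot(is(chm1, "SurfaceGrid"))
    if (!gridsAligned(chm1, labels1)) .stop_misaligned("matchLoss (chm1)")
    cut <- diffSeg$minLossHeight %||% 3
    lv <- labels1@values
    supp <- which(is.finite(lv) & lv > 0 & is.finite(chm1@values) &
                  chm1@values >= cut)
    if (length(supp)) {
      tab <- table(factor(lv[supp], levels = crowns1$id))
      crownArea <- as.numeric(tab) * labels1@resolution^2
    } else {
      crownArea <- rep(0, nrow(crowns1))
    }
  }

  sv <- dl@values; cv <- labels1@values
  sel <- which(is.finite(sv) & sv > 0 & is.finite(cv) & cv > 0)
  if (!length(sel)) return(empty)
  ov <- data.table(seg = as.integer(sv[sel]), crown = as.integer(cv[sel]))
  ov <- ov[, .N, by = .(seg, crown)]

  # best crown per segment: max overlap, ties by height delta then crown id
  ov[, seg_height := segs$height[match(seg, segs$id)]]
  ov[, seg_area := segs$area[match(seg, segs$id)]]
  ov[, crown_height := crowns1$height[match(crown, crowns1$id)]]
  ov[, crown_area := crownArea[match(crown, crowns1$id)]]
  ov[, hdelta := abs(crown_height - seg_height)]
  setorder(ov, seg, -N, hdelta, crown)
  best <- ov[, .SD[1], by = seg]

  best[, area_ratio := abs(crown_area - seg_area) / crown_area]
  cand <- best[hdelta < heightTol & area_ratio < areaTol]
  if (!nrow(cand)) return(empty)

  # at most one event per first-epoch crown
  setorder(cand, crown, hdelta, seg)
  cand <- cand[, .SD[1], by = crown]
  setorder(cand, seg)
  data.frame(id_1 = cand$crown, diff_segment_id = cand$seg,
             height_delta_match = cand$hdelta,
             area_ratio_delta = cand$area_ratio,
             height_1 = cand$crown_height)
}

# ---- rates ------------------------------------------------------------------

#' Tree-loss rate by height class
#'
#' Per height class of the first-epoch crown table: the number of detected
#' loss events divided by the number of crowns. The overall rate is also
#' annualised two ways — linear (`rate / intervalYears`) and compound
#' (`1 - (1 - rate)^(1/intervalYears)`) — since both conventions are in use
#' for multi-year removal rates.
#'
#' @param events loss-event table from [matchLoss()].
#' @param crowns1 epoch-1 crown table.
#' @param binWidth class width, metres.
#' @param intervalYears observation interval, years.
#' @return list: `byClass` (data.frame `binLower`, `binUpper`, `nCrowns`,
#'   `nLost`, `rate`), `overall`, `annualLinear`, `annualCompound`.
#' @export
lossRateByClass <- function(events, crowns1, binWidth = 5,
                            intervalYears = 5) {
  bin <- floor(crowns1$height / binWidth)
  tab <- as.data.frame(table(bin))
  tab$bin <- as.numeric(as.character(tab$bin))
  lostBin <- floor(events$height_1 / binWidth)
  lostTab <- table(lostBin)
  tab$nLost <- as.integer(lostTab[as.character(tab$bin)])
  tab$nLost[is.na(tab$nLost)] <- 0L
  byClass <- data.frame(
    binLower = tab$bin * binWidth, binUpper = (tab$bin + 1) * binWidth,
    nCrowns = tab$Freq, nLost = tab$nLost,
    rate = tab$nLost / tab$Freq
  )
  byClass <- byClass[order(byClass$binLower), , drop = FALSE]
  overall <- nrow(events) / nrow(crowns1)
  list(byClass = byClass, overall = overall,
       annualLinear = overall / intervalYears,
       annualCompound = 1 - (1 - overall)^(1 / intervalYears))
}

#' Site-level count-based loss
#'
#' The coarse, histogram-style loss estimate: the difference in delineated
#' crown counts between epochs and that difference as a fraction of the
#' first epoch's count. A negative difference is a net gain.
#'
#' @param crowns1,crowns2 crown tables (or plain counts).
#' @return list: `n_1`, `n_2`, `difference`, `fraction`.
#' @examples
#' countBasedLoss(87913, 79078)  # difference 8835, fraction ~0.1
#' @export
countBasedLoss <- function(crowns1, crowns2) {
  n1 <- if (is.data.frame(crowns1)) nrow(crowns1) else as.numeric(crowns1)
  n2 <- if (is.data.frame(crowns2)) nrow(crowns2) else as.numeric(crowns2)
  list(n_1 = n1, n_2 = n2, difference = n1 - n2, fraction = (n1 - n2) / n1)
}

utils::globalVariables(c(
  "seg", "crown", "seg_height", "seg_area", "crown_height", "crown_area",
  "hdelta", "area_ratio", ".SD", ".I", "orig", "keeprow", "zmax"
))
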