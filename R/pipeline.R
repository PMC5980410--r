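# ---- configuration ----------------------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable of the change-detection chain with defaults
#' matching the method's stated parameters: +/-15 degree scan-angle window,
#' growth filters at 5 m height change, 1 m DEM difference and 100% radius
#' change, loss matching at 3 m height and 30% area agreement. Unknown
#' arguments are rejected. Configurations round-trip through YAML unchanged.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A named list of class `PipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(resolution = 1, seed = 42)
#' cfg$maxScanAngle
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    # inputs (paths; in-memory objects can be passed to runPipeline directly)
    cloud1Path = NULL, cloud2Path = NULL, gcpPath = NULL, fieldPath = NULL,
    # surfaces
    resolution = 0.5, smoothingSigma = 0.5, splatRadius = 0.25,
    coarseRes = 5, groundTol = 0.3, demTileSize = 10,
    # delineation
    minTreeHeight = 2, windowRadius = 1, maxLayers = 4,
    gapBinWidth = 0.5, gapMin = 2, gapMinFraction = 0.1, gapMinPoints = 10,
    # change preparation
    maxScanAngle = 15, equalizeDensity = TRUE,
    maxDHeight = 5, maxDDem = 1, maxRadiusChange = 1.0,
    requireReciprocal = TRUE,
    # loss detection
    minLossHeight = 3, lossHeightTol = 3, lossAreaTol = 0.30,
    # analysis
    binWidth = 5, minN = 20, heightFloor = 50, intervalYears = 5,
    sigmaHtEstimator = "meanabs", totalMethod = "linear",
    changeMethod = "quadrature",
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  num <- c("resolution", "smoothingSigma", "coarseRes", "groundTol",
           "demTileSize", "minTreeHeight", "gapBinWidth", "gapMin",
           "maxScanAngle", "maxDHeight", "maxDDem", "maxRadiusChange",
           "minLossHeight", "lossHeightTol", "lossAreaTol", "binWidth",
           "intervalYears")
  if (any(unlist(cfg[num]) <= 0)) {
    stop("all thresholds and sizes must be positive", call. = FALSE)
  }
  structure(cfg, class = "PipelineConfig")
}

#' Save / load a pipeline configuration as YAML
#'
#' @param config a `PipelineConfig`.
#' @param path YAML file path.
#' @return `saveConfig` returns `path` invisibly; `loadConfig` the
#'   configuration.
#' @export
saveConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  do.call(pipelineConfig, vals)
}

# ---- synthetic study --------------------------------------------------------

#' Simulate a complete two-epoch study over a synthetic forest
#'
#' Generates a scene, applies a change scenario, simulates both
#' acquisitions, and derives ground control points from the apices of the
#' tallest surviving trees (as a manual image-to-image registration would),
#' jittered by a small digitisation error.
#'
#' @param nTrees number of trees.
#' @param extent scene size, metres.
#' @param scenario a `ChangeScenario`.
#' @param spec1,spec2 `AcquisitionSpec`s for the two epochs.
#' @param seed master seed; scene, scenario and acquisition seeds derive
#'   from it.
#' @param nGcp number of ground control points.
#' @param gcpJitterSd digitisation jitter on each GCP coordinate, metres.
#' @param ... passed to [generateScene()].
#' @return list: `scene1`, `scene2`, `truth`, `cloud1`, `cloud2`, `gcps`.
#' @export
simulateStudy <- function(nTrees, extent = c(200, 200),
                          scenario = changeScenario(),
                          spec1 = acquisitionSpec(returnDensity = 18,
                                                  footprintDiameter = 0.15),
                          spec2 = acquisitionSpec(returnDensity = 13,
                                                  footprintDiameter = 0.10,
                                                  horizontalOffset = c(1.0, -0.7)),
                          seed = 1L, nGcp = 50L, gcpJitterSd = 0.05, ...) {
  seed <- as.integer(seed)
  scene1 <- generateScene(nTrees, extent = extent, seed = seed, ...)
  scenario$seed <- seed + 1000L
  ch <- applyChange(scene1, scenario)
  spec1$seed <- seed + 2000L
  spec2$seed <- seed + 3000L
  cloud1 <- simulateAcquisition(scene1, spec1)
  cloud2 <- simulateAcquisition(ch$scene2, spec2)

  surv <- ch$truth[!ch$truth$removed, ]
  surv <- surv[order(-surv$height_1), ]
  nG <- min(nGcp, nrow(surv))
  gg <- surv[seq_len(nG), ]
  gcps <- withr::with_seed(seed + 4000L, data.frame(
    src_x = gg$x + spec2$horizontalOffset[1] + rnorm(nG, 0, gcpJitterSd),
    src_y = gg$y + spec2$horizontalOffset[2] + rnorm(nG, 0, gcpJitterSd),
    dst_x = gg$x + rnorm(nG, 0, gcpJitterSd),
    dst_y = gg$y + rnorm(nG, 0, gcpJitterSd)
  ))
  list(scene1 = scene1, scene2 = ch$scene2, truth = ch$truth,
       cloud1 = cloud1, cloud2 = cloud2, gcps = gcps)
}

# ---- pipeline ---------------------------------------------------------------

.stage <- function(log, name, fmt, ...) {
  line <- sprintf(paste0("[%s] ", fmt), name, ...)
  c(log, line)
}

#' Run the full change-detection pipeline
#'
#' Executes, in order: scan-angle filtering, ground classification and DEM
#' interpolation per epoch, smoothed CHM construction on a common grid,
#' multistory crown delineation per epoch, GCP-based co-registration of the
#' second epoch, centroid-overlay crown matching with the four growth
#' filters, size-class growth summaries, CHM-difference tree-loss detection
#' with size-class rates, and the biomass change with its full error budget.
#' Every stage's sample size is logged.
#'
#' @param config a `PipelineConfig`.
#' @param cloud1,cloud2 point clouds (data.frames); when `NULL` they are
#'   read from the configured paths.
#' @param gcps ground-control-point table (`src_x`, `src_y`, `dst_x`,
#'   `dst_y`); `NULL` reads from the configured path; `NA` skips
#'   registration (identity transform).
#' @param field optional field table (`height_m`, `dbh_cm`) to fit the DBH
#'   model; defaults to the packaged site model.
#' @return A result bundle (list of class `canopychangeResults`): crown
#'   tables, label grids, match and loss tables, growth and loss summaries,
#'   biomass totals with the error budget, the registration transform, and
#'   the stage log.
#' @seealso [makeReport()] to render the bundle.
#' @export
runPipeline <- function(config = pipelineConfig(), cloud1 = NULL,
                        cloud2 = NULL, gcps = NULL, field = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- character()
  if (is.null(cloud1)) {
    if (is.null(config$cloud1Path)) stop("no epoch-1 cloud", call. = FALSE)
    cloud1 <- readCloud(config$cloud1Path)
  }
  if (is.null(cloud2)) {
    if (is.null(config$cloud2Path)) stop("no epoch-2 cloud", call. = FALSE)
    cloud2 <- readCloud(config$cloud2Path)
  }
  if (is.null(gcps) && !is.null(config$gcpPath)) {
    gcps <- readTable(config$gcpPath)
  }
  if (is.null(field) && !is.null(config$fieldPath)) {
    field <- readTable(config$fieldPath)
  }

  # 1. scan-angle filter
  c1 <- filterScanAngle(cloud1, config$maxScanAngle)
  c2 <- filterScanAngle(cloud2, config$maxScanAngle)
  log <- .stage(log, "scan_angle", "epoch1 %d -> %d, epoch2 %d -> %d returns",
                nrow(cloud1), nrow(c1), nrow(cloud2), nrow(c2))
  if (isTRUE(config$equalizeDensity)) {
    eq <- equalizeDensity(c1, c2, seed = config$seed)
    c1 <- eq$cloud1; c2 <- eq$cloud2
    log <- .stage(log, "density", "equalised to common density (kept %.2f / %.2f); %d / %d returns",
                  attr(eq, "kept")[1], attr(eq, "kept")[2], nrow(c1),
                  nrow(c2))
  }

  # 2. common grid from the union of filtered extents
  ext <- c(min(c1$x, c2$x), max(c1$x, c2$x), min(c1$y, c2$y), max(c1$y, c2$y))

  # 3. ground + DEM per epoch on the shared grid
  g1 <- classifyGround(c1, config$coarseRes, config$groundTol)
  g2 <- classifyGround(c2, config$coarseRes, config$groundTol)
  dem1 <- buildDEM(g1, config$resolution, extent = ext,
                   tileSize = config$demTileSize)
  dem2 <- buildDEM(g2, config$resolution, extent = ext,
                   tileSize = config$demTileSize)
  log <- .stage(log, "ground", "epoch1 %d, epoch2 %d ground returns",
                nrow(g1), nrow(g2))

  # 4. CHMs (epoch 2 on its own DEM, same grid geometry)
  chm1 <- buildCHM(c1, dem1, smoothingSigma = config$smoothingSigma,
                   splatRadius = config$splatRadius)
  chm2 <- buildCHM(c2, dem2, smoothingSigma = config$smoothingSigma,
                   splatRadius = config$splatRadius)

  # 5. delineation per epoch
  del1 <- delineateMultistory(chm1, c1, dem1,
                              minTreeHeight = config$minTreeHeight,
                              smoothingSigma = config$smoothingSigma,
                              maxLayers = config$maxLayers,
                              windowRadius = config$windowRadius,
                              binWidth = config$gapBinWidth,
                              minGap = config$gapMin,
                              minFraction = config$gapMinFraction,
                              minPoints = config$gapMinPoints)
  del2 <- delineateMultistory(chm2, c2, dem2,
                              minTreeHeight = config$minTreeHeight,
                              smoothingSigma = config$smoothingSigma,
                              maxLayers = config$maxLayers,
                              windowRadius = config$windowRadius,
                              binWidth = config$gapBinWidth,
                              minGap = config$gapMin,
                              minFraction = config$gapMinFraction,
                              minPoints = config$gapMinPoints)
  log <- .stage(log, "delineation", "epoch1 %d crowns (%d layers), epoch2 %d crowns (%d layers)",
                nrow(del1$crowns), del1$nLayers, nrow(del2$crowns),
                del2$nLayers)

  # 6. registration of epoch 2 onto the epoch-1 frame
  transform <- if (is.null(gcps) || (length(gcps) == 1L && is.na(gcps))) {
    affineTransform(rmse = 0)
  } else {
    fitRegistration(gcps)
  }
  crowns2reg <- applyTransform(del2$crowns, transform)
  chm2reg <- applyTransform(chm2, transform, reference = chm1)
  dem2reg <- applyTransform(dem2, transform, reference = dem1)
  labels2reg <- lapply(del2$labels, applyTransform, transform = transform,
                       reference = chm1)
  log <- .stage(log, "registration", "affine fit RMSE %.3f m",
                transform@rmse)

  # 7. matching per layer + growth filters
  nLay <- min(length(del1$labels), length(labels2reg))
  matches <- do.call(rbind, lapply(seq_len(nLay), function(i) {
    lay <- i - 1L
    matchCrowns(del1$crowns[del1$crowns$layer == lay, , drop = FALSE],
                labels2reg[[i]],
                crowns2reg[crowns2reg$layer == lay, , drop = FALSE],
                labels1 = del1$labels[[i]], dem1 = dem1, dem2 = dem2reg)
  }))
  filt <- applyGrowthFilters(matches, maxDHeight = config$maxDHeight,
                             maxDDem = config$maxDDem,
                             maxRadiusChange = config$maxRadiusChange,
                             requireReciprocal = config$requireReciprocal)
  log <- .stage(log, "matching", "%d matches, %d retained after filters (%s)",
                nrow(matches), nrow(filt$matches),
                paste(names(filt$counts$marginal), filt$counts$marginal,
                      sep = "=", collapse = ", "))

  # 8. growth summaries
  growth <- growthBySize(filt$matches, config$binWidth, config$minN)
  radius <- radiusChangeBySize(filt$matches, config$binWidth, config$minN)

  # 9. loss detection on the difference surface (layer-0 crowns)
  diffGrid <- differenceCHM(chm1, chm2reg)
  diffSeg <- segmentDifference(diffGrid, config$minLossHeight,
                               config$windowRadius)
  crowns1l0 <- del1$crowns[del1$crowns$layer == 0L, , drop = FALSE]
  events <- matchLoss(diffSeg, crowns1l0, del1$labels[[1]], chm1 = chm1,
                      heightTol = config$lossHeightTol,
                      areaTol = config$lossAreaTol)
  lossRates <- lossRateByClass(events, crowns1l0, config$binWidth,
                               config$intervalYears)
  counts <- countBasedLoss(del1$crowns, del2$crowns)
  log <- .stage(log, "loss", "%d difference segments, %d loss events; count difference %d",
                nrow(diffSeg$segments), nrow(events), counts$difference)

  # 10. biomass and error budget
  model <- if (!is.null(field)) fitDbhModel(field) else {
    m <- allometricModel()
    # without a field fit the site defaults carry a nominal parameter error
    allometricModel(a = m@a, sigmaA = 0.063 * m@a, rmseDbh = m@rmseDbh)
  }
  sigmaHt <- tryCatch(
    heightMeasurementError(filt$matches, config$heightFloor,
                           config$sigmaHtEstimator),
    error = function(e) {
      log <<- .stage(log, "sigma_ht", "WARNING: %s", conditionMessage(e))
      NA_real_
    })
  budget1 <- budget2 <- totals <- NULL
  if (is.finite(sigmaHt)) {
    budget1 <- errorBudget(del1$crowns$height, model, sigmaHt,
                           config$totalMethod)
    budget2 <- errorBudget(del2$crowns$height, model, sigmaHt,
                           config$totalMethod)
    totals <- aggregateTotals(budget1@perTree$biomass,
                              budget1@perTree$sigmaAgb,
                              budget2@perTree$biomass,
                              budget2@perTree$sigmaAgb,
                              config$totalMethod, config$changeMethod)
    log <- .stage(log, "biomass", "totals %.4g / %.4g kg, change %.4g +/- %.4g kg",
                  totals$total_1, totals$total_2, totals$agbChange,
                  totals$sigmaChange)
  }
  classChange <- biomassChangeByClass(filt$matches, events, model,
                                      config$binWidth)

  structure(list(
    config = config, transform = transform,
    dem1 = dem1, dem2 = dem2reg, chm1 = chm1, chm2 = chm2reg,
    diff = diffGrid,
    crowns1 = del1$crowns, crowns2 = del2$crowns, crowns2reg = crowns2reg,
    labels1 = del1$labels, labels2 = labels2reg,
    matches = matches, filtered = filt, growth = growth, radius = radius,
    diffSegments = diffSeg$segments, lossEvents = events,
    lossRates = lossRates, counts = counts,
    model = model, sigmaHt = sigmaHt,
    budget1 = budget1, budget2 = budget2, totals = totals,
    biomassByClass = classChange, log = log
  ), class = "canopychangeResults")
}

#' @export
print.canopychangeResults <- function(x, ...) {
  cat("canopychange result bundle\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

# ---- report -----------------------------------------------------------------

#' Render a human-readable summary of a result bundle
#'
#' Prints epoch crown counts, mean heights and CHM means, the filter
#' attrition, the growth and loss summaries by size class, and the biomass
#' change with its error decomposition. Every number comes from tables
#' already present in the bundle; nothing is recomputed, so regeneration is
#' idempotent.
#'
#' @param bundle a `canopychangeResults` from [runPipeline()].
#' @return The report as a character vector of lines, invisibly; also
#'   printed.
#' @export
makeReport <- function(bundle) {
  stopifnot(inherits(bundle, "canopychangeResults"))
  need <- c("crowns1", "crowns2", "counts", "filtered", "lossRates")
  if (!all(need %in% names(bundle))) {
    stop("incomplete bundle: missing ",
         paste(setdiff(need, names(bundle)), collapse = ", "), call. = FALSE)
  }
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  cm1 <- mean(gridValues(bundle$chm1), na.rm = TRUE)
  cm2 <- mean(gridValues(bundle$chm2), na.rm = TRUE)
  add("== Crown delineation ==")
  add("crowns epoch 1: %d   epoch 2: %d", nrow(bundle$crowns1),
      nrow(bundle$crowns2))
  add("count difference: %d (%.1f%% of epoch 1)", bundle$counts$difference,
      100 * bundle$counts$fraction)
  add("mean crown height: %.2f m -> %.2f m", mean(bundle$crowns1$height),
      mean(bundle$crowns2$height))
  add("mean CHM value: %.2f m -> %.2f m (mean change %.2f m)", cm1, cm2,
      cm2 - cm1)
  add("")
  add("== Growth (matched crowns) ==")
  add("matches: %d, retained after filters: %d",
      bundle$filtered$counts$n_in, bundle$filtered$counts$n_retained)
  excl <- bundle$filtered$counts$marginal
  add("marginal exclusions: %s",
      paste(names(excl), excl, sep = "=", collapse = ", "))
  if (nrow(bundle$filtered$matches)) {
    add("mean height growth of retained matches: %.2f m",
        mean(bundle$filtered$matches$d_height))
  }
  g <- bundle$growth$summary
  if (nrow(g)) {
    add("height-growth medians by class (Spearman rho %.2f, p %.2g):",
        bundle$growth$spearmanRho, bundle$growth$spearmanP)
    for (i in seq_len(nrow(g))) {
      add("  %2.0f-%2.0f m  n=%-5d median %+.2f m  [p10 %+.2f, p90 %+.2f]",
          g$binLower[i], g$binUpper[i], g$n[i], g$median[i], g$p10[i],
          g$p90[i])
    }
  }
  add("")
  add("== Tree loss ==")
  if (nrow(bundle$lossEvents)) {
    add("detected loss events: %d (watershed) vs count difference %d",
        nrow(bundle$lossEvents), bundle$counts$difference)
  } else {
    add("no tree losses detected")
  }
  lr <- bundle$lossRates
  add("overall loss rate: %.1f%% over the interval (%.2f%%/yr linear, %.2f%%/yr compound)",
      100 * lr$overall, 100 * lr$annualLinear, 100 * lr$annualCompound)
  bc <- lr$byClass
  for (i in seq_len(nrow(bc))) {
    add("  %2.0f-%2.0f m  %5d crowns  %4d lost  rate %.1f%%",
        bc$binLower[i], bc$binUpper[i], bc$nCrowns[i], bc$nLost[i],
        100 * bc$rate[i])
  }
  add("")
  add("== Biomass ==")
  if (!is.null(bundle$totals)) {
    t <- bundle$totals
    add("total biomass: %.4g +/- %.4g kg (%.0f%%) -> %.4g +/- %.4g kg (%.0f%%)",
        t$total_1, t$sigmaTotal_1, 100 * t$frac_1, t$total_2,
        t$sigmaTotal_2, 100 * t$frac_2)
    add("biomass change: %.4g +/- %.4g kg (%.0f%%)", t$agbChange,
        t$sigmaChange,
        100 * t$sigmaChange / max(abs(t$agbChange), .Machine$double.eps))
    b <- bundle$budget1
    add("mean per-tree fractional errors: height %.1f%%, parameter %.1f%%, residual %.1f%%, DBH %.1f%%",
        100 * mean(b@perTree$fracHt), 100 * mean(b@perTree$fracParam),
        100 * mean(b@perTree$fracResid), 100 * mean(b@perTree$fracDbh))
    add("allometric fit CV: %.1f%%", 100 * allometricFitCV(bundle$model))
  } else {
    add("biomass budget unavailable (height measurement error not estimable)")
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
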