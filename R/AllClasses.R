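#' Georeferenced single-band raster grid
#'
#' A minimal raster container used for DEMs, canopy height models (CHM), CHM
#' differences and integer label images. The grid origin is the lower-left
#' corner of the lower-left cell: cell `(row, col)` (1-based) covers the
#' half-open square `[x0+(col-1)*res, x0+col*res) x [y0+(row-1)*res,
#' y0+row*res)`, so row 1 is the southernmost row. Nodata is represented as
#' `NA`; it propagates through every operation and is never silently treated
#' as zero.
#'
#' @slot values numeric matrix of cell values (metres for DEM/CHM/DIFF,
#'   integer crown labels for LABELS); `NA` marks nodata.
#' @slot origin numeric length-2, `(x0, y0)` of the lower-left corner, metres.
#' @slot resolution positive number, metres per cell side.
#' @slot kind one of `"DEM"`, `"CHM"`, `"DIFF"`, `"LABELS"`.
#' @exportClass SurfaceGrid
setClass("SurfaceGrid",
  representation(
    values = "matrix",
    origin = "numeric",
    resolution = "numeric",
    kind = "character"
  )
)

setValidity("SurfaceGrid", function(object) {
  msg <- character()
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0) {
    msg <- c(msg, "resolution must be a single positive number")
  }
  if (length(object@origin) != 2L || any(!is.finite(object@origin))) {
    msg <- c(msg, "origin must be two finite numbers (x0, y0)")
  }
  if (length(object@kind) != 1L ||
      !object@kind %in% c("DEM", "CHM", "DIFF", "LABELS")) {
    msg <- c(msg, "kind must be one of DEM, CHM, DIFF, LABELS")
  }
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.numeric(v) && identical(object@kind, "CHM")) {
    ok <- v[is.finite(v)]
    if (length(ok) && min(ok) < -1e-9) {
      msg <- c(msg, "CHM values must be >= 0 where valid")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SurfaceGrid
#'
#' @param values numeric matrix, row 1 = southernmost row.
#' @param origin `(x0, y0)` of the lower-left corner in metres.
#' @param resolution cell size in metres.
#' @param kind grid kind: `"DEM"`, `"CHM"`, `"DIFF"` or `"LABELS"`.
#' @return A [SurfaceGrid-class] object.
#' @examples
#' g <- surfaceGrid(matrix(0, 10, 10), c(0, 0), 0.5, "CHM")
#' gridResolution(g)
#' @export
surfaceGrid <- function(values, origin = c(0, 0), resolution = 0.5,
                        kind = c("CHM", "DEM", "DIFF", "LABELS")) {
  kind <- match.arg(kind)
  storage.mode(values) <- "double"
  new("SurfaceGrid", values = values, origin = as.numeric(origin),
      resolution = as.numeric(resolution), kind = kind)
}

#' @describeIn surfaceGrid Cell values matrix (row 1 = south).
#' @param x a `SurfaceGrid`.
#' @export
gridValues <- function(x) x@values

#' @describeIn surfaceGrid Lower-left corner `(x0, y0)`.
#' @export
gridOrigin <- function(x) x@origin

#' @describeIn surfaceGrid Cell size in metres.
#' @export
gridResolution <- function(x) x@resolution

#' @describeIn surfaceGrid Grid kind string.
#' @export
gridKind <- function(x) x@kind

setMethod("show", "SurfaceGrid", function(object) {
  d <- dim(object@values)
  v <- object@values[is.finite(object@values)]
  cat(sprintf("SurfaceGrid [%s] %d rows x %d cols @ %g m\n", object@kind,
              d[1], d[2], object@resolution))
  cat(sprintf("  origin (%g, %g); %d nodata cells\n", object@origin[1],
              object@origin[2], sum(!is.finite(object@values))))
  if (length(v)) {
    cat(sprintf("  values: min %.3f, mean %.3f, max %.3f\n", min(v), mean(v),
                max(v)))
  }
  invisible(object)
})

#' Test whether two grids share origin, resolution and shape
#'
#' Alignment is exact: same origin (to 1e-9 m), same resolution, same matrix
#' dimensions. Operations that combine grids require alignment and never
#' resample implicitly.
#'
#' @param a,b `SurfaceGrid` objects.
#' @return `TRUE` or `FALSE`.
#' @export
gridsAligned <- function(a, b) {
  stopifnot(is(a, "SurfaceGrid"), is(b, "SurfaceGrid"))
  all(abs(a@origin - b@origin) < 1e-9) &&
    abs(a@resolution - b@resolution) < 1e-12 &&
    identical(dim(a@values), dim(b@values))
}

.stop_misaligned <- function(what) {
  stop(what, ": grids are not aligned (same origin, resolution and shape ",
       "required; resample explicitly with applyTransform)", call. = FALSE)
}

# cell centre coordinates for (row, col) matrices
.cell_centres <- function(grid, rows, cols) {
  list(
    x = grid@origin[1] + (cols - 0.5) * grid@resolution,
    y = grid@origin[2] + (rows - 0.5) * grid@resolution
  )
}

# (row, col) containing scene coordinates; 0 when outside
.cell_index <- function(grid, x, y) {
  d <- dim(grid@values)
  col <- floor((x - grid@origin[1]) / grid@resolution) + 1L
  row <- floor((y - grid@origin[2]) / grid@resolution) + 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Allometric model linking tree height, stem diameter and biomass
#'
#' Couples a zero-intercept linear height-to-DBH model (`dbh = a * height`,
#' DBH in cm, height in m) with the Jenkins generalized biomass equation for
#' the true fir/hemlock group, `biomass = exp(b0 + b1 * ln(DBH))` in kg. The
#' residual spread of the biomass equation in log space (`sigmaLog`) is
#' propagated as a lognormal coefficient of variation.
#'
#' @slot a DBH per height slope, cm per m.
#' @slot sigmaA standard error of `a`.
#' @slot rmseDbh residual RMSE of the DBH model, cm.
#' @slot jenkinsB0,jenkinsB1 Jenkins intercept and ln(DBH) exponent.
#' @slot sigmaLog log-space standard error of the Jenkins equation.
#' @exportClass AllometricModel
setClass("AllometricModel",
  representation(
    a = "numeric", sigmaA = "numeric", rmseDbh = "numeric",
    jenkinsB0 = "numeric", jenkinsB1 = "numeric", sigmaLog = "numeric"
  )
)

setValidity("AllometricModel", function(object) {
  msg <- character()
  if (!is.finite(object@a) || object@a <= 0) msg <- c(msg, "a must be > 0")
  if (is.finite(object@sigmaA) && object@sigmaA < 0) {
    msg <- c(msg, "sigmaA must be >= 0")
  }
  if (is.finite(object@rmseDbh) && object@rmseDbh < 0) {
    msg <- c(msg, "rmseDbh must be >= 0")
  }
  if (!is.finite(object@sigmaLog) || object@sigmaLog < 0) {
    msg <- c(msg, "sigmaLog must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an allometric model
#'
#' Defaults are the site model for a mature Sierra Nevada mixed-conifer
#' forest: slope 2.2 cm of DBH per metre of height with 15.5 cm residual RMSE
#' (21.6 %RMSE), and the Jenkins true fir/hemlock coefficients with log-space
#' error 0.182329.
#'
#' @param a DBH slope, cm per m of height.
#' @param sigmaA standard error of `a` (`NA` if unknown).
#' @param rmseDbh residual RMSE of the DBH model, cm.
#' @param jenkinsB0,jenkinsB1 Jenkins equation coefficients.
#' @param sigmaLog log-space standard error of the Jenkins equation.
#' @return An [AllometricModel-class].
#' @examples
#' m <- allometricModel()
#' predictDbh(30, m)      # 66 cm
#' jenkinsBiomass(66)     # kg
#' @export
allometricModel <- function(a = 2.2, sigmaA = NA_real_, rmseDbh = 15.5,
                            jenkinsB0 = -2.5384, jenkinsB1 = 2.4814,
                            sigmaLog = 0.182329) {
  new("AllometricModel", a = a, sigmaA = sigmaA, rmseDbh = rmseDbh,
      jenkinsB0 = jenkinsB0, jenkinsB1 = jenkinsB1, sigmaLog = sigmaLog)
}

setMethod("show", "AllometricModel", function(object) {
  cat(sprintf("AllometricModel: DBH = %.4g * height (sigma_a = %.4g, RMSE = %.4g cm)\n",
              object@a, object@sigmaA, object@rmseDbh))
  cat(sprintf("  biomass = exp(%.4f + %.4f ln DBH), log-space sigma = %.6f\n",
              object@jenkinsB0, object@jenkinsB1, object@sigmaLog))
  invisible(object)
})

#' Per-tree and aggregate biomass error budget
#'
#' Houses the full error-propagation chain: height measurement error,
#' DBH-model parameter and residual errors combined as a fractional
#' root-sum-of-squares into a DBH error, amplified through the Jenkins
#' exponent, combined with the lognormal allometric scatter, and aggregated
#' to site totals and a change estimate.
#'
#' @slot perTree data.frame with one row per tree: `height`, `dbh`, `biomass`,
#'   `fracHt`, `fracParam`, `fracResid`, `fracDbh`, `sigmaMDbh`, `sigmaAllom`,
#'   `sigmaAgb` (masses in kg, fractions dimensionless).
#' @slot sigmaHt height measurement error, metres.
#' @slot total total biomass, kg.
#' @slot sigmaTotal error on the total (linear sum of per-tree errors by
#'   default), kg.
#' @exportClass ErrorBudget
setClass("ErrorBudget",
  representation(
    perTree = "data.frame", sigmaHt = "numeric", total = "numeric",
    sigmaTotal = "numeric"
  )
)

setValidity("ErrorBudget", function(object) {
  pt <- object@perTree
  need <- c("height", "dbh", "biomass", "fracHt", "fracParam", "fracResid",
            "fracDbh", "sigmaMDbh", "sigmaAllom", "sigmaAgb")
  if (!all(need %in% names(pt))) {
    return(paste("perTree must contain columns:", paste(need, collapse = ", ")))
  }
  if (nrow(pt)) {
    sig <- unlist(pt[c("sigmaMDbh", "sigmaAllom", "sigmaAgb")])
    if (any(sig < 0, na.rm = TRUE)) return("per-tree sigmas must be >= 0")
    if (any(pt$sigmaAgb + 1e-9 < pt$sigmaMDbh, na.rm = TRUE)) {
      return("sigmaAgb must be >= sigmaMDbh")
    }
  }
  TRUE
})

setMethod("show", "ErrorBudget", function(object) {
  n <- nrow(object@perTree)
  cat(sprintf("ErrorBudget: %d trees, sigma_ht = %.3f m\n", n, object@sigmaHt))
  cat(sprintf("  total biomass %.4g kg +/- %.4g (%.1f%%)\n", object@total,
              object@sigmaTotal,
              100 * object@sigmaTotal / max(object@total, .Machine$double.eps)))
  if (n) {
    cat(sprintf("  mean fractional errors: ht %.1f%%, param %.1f%%, resid %.1f%%, DBH %.1f%%\n",
                100 * mean(object@perTree$fracHt),
                100 * mean(object@perTree$fracParam),
                100 * mean(object@perTree$fracResid),
                100 * mean(object@perTree$fracDbh)))
  }
  invisible(object)
})

#' Affine planar transform (2x2 linear part + translation)
#'
#' Maps source coordinates into a reference frame:
#' `(x', y')' = A (x, y)' + b`. Used to co-register the second epoch's
#' delineation onto the first epoch's grid.
#'
#' @slot A 2x2 numeric matrix, invertible.
#' @slot b numeric length-2 translation, metres.
#' @slot rmse residual RMSE of the fit, metres (`NA` if not fitted).
#' @exportClass AffineTransform
setClass("AffineTransform",
  representation(A = "matrix", b = "numeric", rmse = "numeric")
)

setValidity("AffineTransform", function(object) {
  if (!identical(dim(object@A), c(2L, 2L))) return("A must be 2x2")
  if (abs(det(object@A)) < 1e-12) return("A must be invertible")
  if (length(object@b) != 2L) return("b must have length 2")
  TRUE
})

#' Construct an affine transform
#'
#' @param A 2x2 linear part.
#' @param b translation vector, metres.
#' @param rmse optional residual RMSE from fitting.
#' @return An [AffineTransform-class].
#' @export
affineTransform <- function(A = diag(2), b = c(0, 0), rmse = NA_real_) {
  new("AffineTransform", A = A, b = as.numeric(b), rmse = rmse)
}

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform:\n")
  cat(sprintf("  A = [%.6f %.6f; %.6f %.6f]\n", object@A[1, 1], object@A[1, 2],
              object@A[2, 1], object@A[2, 2]))
  cat(sprintf("  b = (%.4f, %.4f) m; fit RMSE = %.4g m\n", object@b[1],
              object@b[2], object@rmse))
  invisible(object)
})

#' Invert an affine transform
#' @param transform an [AffineTransform-class].
#' @return The inverse transform.
#' @export
invertTransform <- function(transform) {
  Ai <- solve(transform@A)
  affineTransform(A = Ai, b = as.numeric(-Ai %*% transform@b),
                  rmse = transform@rmse)
}

# apply to coordinate vectors; returns list(x, y)
.transform_xy <- function(transform, x, y) {
  list(
    x = transform@A[1, 1] * x + transform@A[1, 2] * y + transform@b[1],
    y = transform@A[2, 1] * x + transform@A[2, 2] * y + transform@b[2]
  )
}
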