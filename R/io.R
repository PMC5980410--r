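#' Write a point cloud to delimited text
#'
#' Clouds are plain tab-separated tables with a header line
#' `x  y  z  scan_angle` (coordinates in metres, scan angle in degrees).
#' Full double precision is preserved, so a write/read round trip is exact.
#'
#' @param cloud data.frame with columns `x`, `y`, `z`, `scan_angle`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readCloud()]
#' @export
writeCloud <- function(cloud, path) {
  cloud <- as.data.table(cloud)
  need <- c("x", "y", "z", "scan_angle")
  if (!all(need %in% names(cloud))) {
    stop("cloud must have columns x, y, z, scan_angle", call. = FALSE)
  }
  fwrite(cloud[, need, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Read a point cloud from delimited text
#'
#' Accepts the tab/comma/whitespace-delimited format written by
#' [writeCloud()]. Non-numeric entries are reported with the offending data
#' row number.
#'
#' @param path input file path.
#' @return data.frame with columns `x`, `y`, `z`, `scan_angle`.
#' @export
readCloud <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- fread(path, colClasses = "character")
  need <- c("x", "y", "z", "scan_angle")
  if (!all(need %in% names(dt))) {
    stop("malformed cloud file ", path, ": header must name columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- dt[, lapply(.SD, function(col) suppressWarnings(as.numeric(col))),
            .SDcols = need]
  if (nrow(out)) {
    bad <- which(rowSums(is.na(out)) > 0)
    if (length(bad)) {
      stop("malformed cloud file ", path, ": non-numeric value in data row ",
           bad[1], call. = FALSE)
    }
  }
  as.data.frame(out)
}

#' Write a SurfaceGrid as an ESRI ASCII raster
#'
#' The ESRI ASCII (`.asc`) format is a plain-text single-band raster with a
#' six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows from north to south. Values are written
#' with full `%.10g` precision.
#'
#' @param grid a [SurfaceGrid-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readGrid()]
#' @export
writeGrid <- function(grid, path) {
  stopifnot(is(grid, "SurfaceGrid"))
  v <- grid@values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid@origin[1]),
    sprintf("yllcorner %.10g", grid@origin[2]),
    sprintf("cellsize %.10g", grid@resolution),
    "NODATA_value -9999"
  )
  v[!is.finite(v)] <- -9999
  # .asc rows run north to south; internal row 1 is the southernmost
  rows <- vapply(seq_len(nr), function(i) {
    paste(sprintf("%.10g", v[nr - i + 1L, ]), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII raster into a SurfaceGrid
#'
#' @param path input `.asc` path.
#' @param kind grid kind to stamp on the result (the format itself does not
#'   record one).
#' @return A [SurfaceGrid-class].
#' @export
readGrid <- function(path, kind = c("CHM", "DEM", "DIFF", "LABELS")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)) || any(is.na(unlist(hdr[need])))) {
    stop("malformed raster header in ", path, call. = FALSE)
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) {
    stop("malformed raster body in ", path, ": expected ", nr * nc,
         " values, got ", length(body), call. = FALSE)
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]  # back to south-first rows
  m[m == nodata] <- NA_real_
  surfaceGrid(m, origin = c(hdr$xllcorner, hdr$yllcorner),
              resolution = hdr$cellsize, kind = kind)
}

#' Write/read delimited attribute tables
#'
#' Crown tables, truth tables, match tables, ground-control-point tables and
#' loss tables are all stored as tab-separated text with a header line.
#'
#' @param table data.frame.
#' @param path file path.
#' @return `writeTable` returns `path` invisibly; `readTable` a data.frame.
#' @export
writeTable <- function(table, path) {
  fwrite(as.data.table(table), path, sep = "\t")
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  as.data.frame(fread(path))
}
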