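# Lightweight in-memory raster grids with plain-text (ESRI ASCII grid) I/O.
#
# Values are stored as a rows x cols matrix with row 1 the TOP of the grid
# (row-major, top-left origin). Coordinates are projected; cell centers sit at
# x = xll + (col - 0.5) * cellsize, y = yll + (nrows - row + 0.5) * cellsize.

#' Construct a raster grid
#'
#' @param values numeric matrix (row 1 = northernmost row)
#' @param xll,yll coordinates of the lower-left corner of the grid
#' @param cellsize cell edge length in projected units (> 0)
#' @param nodata sentinel written on export; internally `NA` marks nodata
#' @param crs free-text tag for the projected CRS (not interpreted)
#' @return object of class `grid_raster`
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cellsize = 1,
                        nodata = -9999, crs = "") {
  values <- as.matrix(values)
  if (cellsize <= 0) stop("cellsize must be > 0")
  if (any(is.infinite(values))) stop("raster values must be finite or NA")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         nodata = nodata, crs = crs),
    class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("grid_raster %d x %d, cellsize %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll))
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Cell-center coordinates for (row, col) indices
#' @param r grid_raster
#' @param row,col 1-based indices (row 1 = top)
#' @return two-column matrix of x, y
#' @export
cell_center <- function(r, row, col) {
  nr <- nrow(r$values)
  cbind(x = r$xll + (col - 0.5) * r$cellsize,
        y = r$yll + (nr - row + 0.5) * r$cellsize)
}

#' Containing-cell lookup for projected coordinates
#'
#' No interpolation: each point maps to the cell whose extent contains it
#' (points exactly on an interior cell edge belong to the cell right/below in
#' x / above in y, via floor on the fractional index).
#'
#' @param r grid_raster
#' @param xy two-column matrix/data.frame of x, y
#' @return data.frame with row, col (1-based) and the cell value
#' @export
cell_at <- function(r, xy) {
  xy <- as.matrix(xy)
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((xy[, 1] - r$xll) / r$cellsize) + 1
  row <- nr - floor((xy[, 2] - r$yll) / r$cellsize)
  # points sitting exactly on the top/right outer boundary belong to the grid
  col[xy[, 1] == r$xll + nc * r$cellsize] <- nc
  row[xy[, 2] == r$yll + nr * r$cellsize] <- 1
  if (any(col < 1 | col > nc | row < 1 | row > nr))
    stop("coordinates fall outside the raster extent")
  data.frame(row = row, col = col,
             value = r$values[cbind(row, col)])
}

#' Extract raster values at coordinates (containing cell, no interpolation)
#' @inheritParams cell_at
#' @return numeric vector of cell values
#' @export
extract_at <- function(r, xy) cell_at(r, xy)$value

#' Read / write ESRI ASCII grid (.asc), a plain-text raster format
#'
#' @param path file path
#' @param crs optional CRS tag attached on read
#' @return `read_ascii_grid` returns a grid_raster; `write_ascii_grid`
#'   invisibly returns the path
#' @export
read_ascii_grid <- function(path, crs = "") {
  if (!file.exists(path)) stop("raster file not found: ", path)
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = h["nrows"], ncol = h["ncols"], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA
  grid_raster(m, xll = h[["xllcorner"]], yll = h[["yllcorner"]],
              cellsize = h[["cellsize"]], nodata = h[["nodata_value"]],
              crs = crs)
}

#' @rdname read_ascii_grid
#' @param r grid_raster to write
#' @export
write_ascii_grid <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", format(r$xll, digits = 15)),
    paste("yllcorner", format(r$yll, digits = 15)),
    paste("cellsize", format(r$cellsize, digits = 15)),
    paste("NODATA_value", r$nodata)), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(format(v[i, ], digits = 10, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

# Assert two rasters share grid geometry.
check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$cellsize - b$cellsize) > 1e-9 ||
      abs(a$xll - b$xll) > 1e-6 || abs(a$yll - b$yll) > 1e-6)
    stop("rasters are not on the same grid")
  invisible(TRUE)
}

#' Lag-1 spatial autocorrelation of a raster
#'
#' Pearson correlation between values of rook-adjacent cell pairs (horizontal
#' and vertical pooled); a simple Moran-type diagnostic used to validate the
#' simulated environmental surfaces.
#'
#' @param r grid_raster or numeric matrix
#' @return scalar correlation
#' @export
lag1_autocorrelation <- function(r) {
  v <- if (inherits(r, "grid_raster")) r$values else as.matrix(r)
  h <- cbind(as.vector(v[, -ncol(v)]), as.vector(v[, -1]))
  ve <- cbind(as.vector(v[-nrow(v), ]), as.vector(v[-1, ]))
  pairs <- rbind(h, ve)
  pairs <- pairs[complete.cases(pairs), , drop = FALSE]
  cor(pairs[, 1], pairs[, 2])
}
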