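#' Create a raster grid
#'
#' A lightweight in-memory raster: a numeric matrix with a cell size, a
#' top-left origin in a projected CRS (meters), and a CRS identifier. Row 1 is
#' the north edge; indices are 1-based; the center of cell (r, c) is at
#' `(origin[1] + (c - 0.5) * cell_size, origin[2] - (r - 0.5) * cell_size)`.
#' Nodata cells are stored as `NA`.
#'
#' @param values numeric matrix (row 1 = north edge).
#' @param cell_size cell edge length in meters.
#' @param origin numeric length-2, (x, y) of the top-left corner.
#' @param crs CRS identifier, e.g. `"EPSG:26918"`; must be a projected CRS in
#'   meters.
#' @param nodata sentinel value used when the grid is written to disk.
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(values, cell_size = 30,
                        origin = c(0, nrow(values) * cell_size),
                        crs = "EPSG:26918", nodata = -9999) {
  stopifnot(is.matrix(values), cell_size > 0, length(origin) == 2)
  check_projected_crs(crs)
  structure(
    list(values = values, cell_size = cell_size,
         origin = as.numeric(origin), crs = crs, nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, %g m, origin (%g, %g), %s\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], x$crs))
  cat(sprintf("  nodata cells: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

check_projected_crs <- function(crs) {
  if (is.null(crs) || is.na(crs) || !nzchar(crs)) {
    stop("CRS is missing; a projected CRS in meters is required", call. = FALSE)
  }
  if (grepl("4326|CRS84|longlat|long/lat", crs, ignore.case = TRUE)) {
    stop("geographic (degree) CRS '", crs,
         "' is not supported; reproject to a projected CRS in meters first",
         call. = FALSE)
  }
  invisible(crs)
}

#' Cell/coordinate transforms
#'
#' `cell_center()` returns the projected coordinates of cell centers;
#' `coord_to_cell()` returns the (row, col) of the cell containing each point.
#' The two are mutual inverses for in-bounds cells.
#'
#' @param grid a [raster_grid()].
#' @param row,col 1-based cell indices (vectorized).
#' @param x,y projected coordinates in meters (vectorized).
#' @return `cell_center()`: a matrix with columns `x`, `y`. `coord_to_cell()`:
#'   a matrix with columns `row`, `col` (`NA` for out-of-bounds points).
#' @export
cell_center <- function(grid, row, col) {
  cbind(x = grid$origin[1] + (col - 0.5) * grid$cell_size,
        y = grid$origin[2] - (row - 0.5) * grid$cell_size)
}

#' @rdname cell_center
#' @export
coord_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((grid$origin[2] - y) / grid$cell_size) + 1L
  bad <- row < 1L | row > nrow(grid$values) | col < 1L | col > ncol(grid$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Value of the cell containing each point
#' @inheritParams cell_center
#' @return numeric vector (`NA` outside the grid or on nodata cells).
#' @export
raster_value_at <- function(grid, x, y) {
  rc <- coord_to_cell(grid, x, y)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- grid$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text ESRI ASCII grid (`.asc`) with a `.prj` sidecar file holding the
#' CRS identifier. Integer-valued grids round-trip bit-exact. A missing `.prj`
#' sidecar is treated as a missing CRS and is an error: the analysis requires
#' a known projected CRS.
#'
#' @param path path to an `.asc` file.
#' @return `read_raster()` returns a [raster_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(kv) == 2 && suppressWarnings(!is.na(as.numeric(kv[2])))) {
      hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  prj <- prj_path(path)
  if (!file.exists(prj)) {
    stop("CRS is missing for ", path, " (no .prj sidecar found); ",
         "a projected CRS in meters is required", call. = FALSE)
  }
  crs <- trimws(readLines(prj, n = 1))
  check_projected_crs(crs)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = 6, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop("expected ", nr * nc, " cells, found ", length(vals), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  raster_grid(m, cell_size = hdr$cellsize,
              origin = c(xll, yll + nr * hdr$cellsize),
              crs = crs, nodata = nodata)
}

#' @rdname read_raster
#' @param grid a [raster_grid()] to write.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  nr <- nrow(m); nc <- ncol(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(grid$origin[1], digits = 15)),
    paste("yllcorner", format(grid$origin[2] - nr * grid$cell_size, digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", format(grid$nodata, digits = 15))
  ), con)
  for (r in seq_len(nr)) {
    writeLines(paste(format(m[r, ], digits = 15, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  writeLines(grid$crs, prj_path(path))
  invisible(path)
}

prj_path <- function(path) sub("\\.[^.]+$", ".prj", path)

#' Fraction of the grid that is nodata
#' @param grid a [raster_grid()].
#' @return fraction in \[0, 1\].
#' @export
nodata_fraction <- function(grid) mean(is.na(grid$values))
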