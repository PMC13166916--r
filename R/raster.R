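#' Create a grid raster
#'
#' A `grid_raster` is a light in-memory raster: a rectangular matrix of cell
#' values on a regular square grid, with the georeferencing needed for the
#' analyses in this package (cell size in metres, lower-left corner, CRS
#' label) and a nodata convention. Row 1 of `values` is the northernmost row;
#' cell identity is the cell centre. Nodata cells are held as `NA` in memory
#' and written out as the `nodata` sentinel.
#'
#' @param values numeric or integer matrix; `NA` marks nodata cells.
#' @param cell_size cell edge length in metres (> 0). Default 30, the grid
#'   resolution at which the index is defined.
#' @param xll,yll coordinates of the lower-left corner of the grid (metres).
#' @param crs free-form CRS identifier (e.g. an EPSG string). Required: grids
#'   without a CRS cannot be co-registered.
#' @param nodata sentinel value used on disk for nodata cells.
#' @param categorical logical; `TRUE` for class-code rasters (land cover),
#'   `FALSE` for continuous fields. Categorical values are stored as integers.
#' @return An object of class `grid_raster`.
#' @examples
#' r <- grid_raster(matrix(runif(25), 5, 5), cell_size = 30, crs = "EPSG:5186")
#' @export
grid_raster <- function(values, cell_size = 30, xll = 0, yll = 0,
                        crs = "local", nodata = -9999, categorical = FALSE) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (is.null(crs) || is.na(crs) || !nzchar(crs))
    stop("`crs` must be a non-empty CRS identifier")
  if (categorical) {
    v <- values
    if (!is.integer(v)) {
      if (any(abs(v - round(v)) > 1e-9, na.rm = TRUE))
        stop("categorical raster values must be whole-number class codes")
      storage.mode(v) <- "integer"
    }
    values <- v
  } else {
    storage.mode(values) <- "double"
  }
  structure(
    list(values = values, cell_size = cell_size, xll = xll, yll = yll,
         crs = crs, nodata = nodata, categorical = categorical),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf(
    "<grid_raster> %d x %d cells @ %g m (%s), %s, %d nodata\n",
    nrow(x$values), ncol(x$values), x$cell_size,
    if (x$categorical) "categorical" else "continuous",
    x$crs, sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

is_grid_raster <- function(x) inherits(x, "grid_raster")

#' @rdname grid_raster
#' @param x a `grid_raster`.
#' @export
raster_values <- function(x) {
  stopifnot(is_grid_raster(x))
  x$values
}

# TRUE when two rasters share shape, cell size and origin (1 mm slack).
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(abs(a$cell_size - b$cell_size) < 1e-3) &&
    isTRUE(abs(a$xll - b$xll) < 1e-3) &&
    isTRUE(abs(a$yll - b$yll) < 1e-3)
}

# Cell-centre coordinates; row 1 is the top (north) row.
cell_centers_x <- function(r) r$xll + (seq_len(ncol(r$values)) - 0.5) * r$cell_size
cell_centers_y <- function(r) r$yll + (nrow(r$values) - seq_len(nrow(r$values)) + 0.5) * r$cell_size

#' Read a raster from an ESRI ASCII grid
#'
#' Reads a `.asc` raster (the plain-text Arc/Info interchange grid: six header
#' lines then rows north to south). The format carries georeferencing and the
#' nodata sentinel but no CRS, so the CRS is taken from a `<path>.prj` sidecar
#' if present, otherwise from the `crs` argument; a raster with neither is an
#' error because it cannot be co-registered with the other inputs.
#'
#' @param path path to the `.asc` file.
#' @param categorical logical; set by the caller according to what the raster
#'   holds (class codes vs a continuous field).
#' @param crs CRS identifier used when no `.prj` sidecar exists.
#' @return A [grid_raster].
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, categorical = FALSE, crs = NULL) {
  if (!file.exists(path)) stop(sprintf("raster file not found: '%s'", path))
  lines <- tryCatch(readLines(path, n = 6L, warn = FALSE),
                    error = function(e) stop(sprintf("cannot read '%s': %s", path, conditionMessage(e))))
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2])))) break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    n_hdr <- n_hdr + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("'%s' is not an ESRI ASCII grid (missing %s)", path,
                 paste(setdiff(need, names(hdr)), collapse = ", ")))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else 0
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("'%s': expected %d cells, found %d", path, nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  prj <- paste0(path, ".prj")
  if (file.exists(prj)) {
    crs <- trimws(readLines(prj, n = 1L, warn = FALSE))
  }
  if (is.null(crs))
    stop(sprintf("raster '%s' has no CRS: no '%s' sidecar and no `crs` argument", path, prj))
  grid_raster(m, cell_size = cs, xll = xll, yll = yll, crs = crs,
              nodata = nodata, categorical = categorical)
}

#' Write a raster to an ESRI ASCII grid
#'
#' Writes `x` as a `.asc` grid plus a `<path>.prj` sidecar holding the CRS
#' identifier. Integer (categorical) rasters round-trip bit-exactly;
#' continuous rasters are printed with 17 significant digits, which also
#' round-trips IEEE doubles exactly.
#'
#' @param x a [grid_raster].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  stopifnot(is_grid_raster(x))
  m <- x$values
  m[is.na(m)] <- x$nodata
  fmt_num <- function(v) {
    if (x$categorical) sprintf("%d", as.integer(v)) else sprintf("%.17g", v)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", ncol(m)),
    sprintf("NROWS %d", nrow(m)),
    sprintf("XLLCORNER %.10g", x$xll),
    sprintf("YLLCORNER %.10g", x$yll),
    sprintf("CELLSIZE %.10g", x$cell_size),
    sprintf("NODATA_VALUE %.10g", x$nodata)
  ), con)
  for (i in seq_len(nrow(m))) writeLines(paste(fmt_num(m[i, ]), collapse = " "), con)
  writeLines(x$crs, paste0(path, ".prj"))
  invisible(path)
}
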