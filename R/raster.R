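#' Regular geographic raster grid
#'
#' A minimal single-layer raster on a regular, axis-aligned longitude/latitude
#' grid. Values are stored row-major from the north-west corner: row 1 is the
#' northernmost row, column 1 the westernmost column, and `NA` marks masked
#' (no-data) cells. Cell centers carry the coordinates.
#'
#' @param values numeric matrix; `NA` = masked cell.
#' @param origin_lon,origin_lat longitude/latitude of the north-west *corner*
#'   of the grid, decimal degrees.
#' @param cell_size_deg cell edge length in decimal degrees (> 0).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_lon = 0, origin_lat = 0, cell_size_deg = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.finite(cell_size_deg) || cell_size_deg <= 0)
    stop("`cell_size_deg` must be > 0", call. = FALSE)
  structure(
    list(values = values,
         origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         cell_size_deg = as.numeric(cell_size_deg)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d x %d cells, %.6g deg/cell, NW corner (%.6g, %.6g)\n",
              nrow(v), ncol(v), x$cell_size_deg, x$origin_lon, x$origin_lat))
  ok <- is.finite(v)
  cat(sprintf("  valid cells: %d/%d; range [%.4g, %.4g]\n",
              sum(ok), length(v),
              if (any(ok)) min(v[ok]) else NA, if (any(ok)) max(v[ok]) else NA))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-center coordinates
#'
#' @param r a `raster_grid`.
#' @param row,col 1-based row/column indices (row 1 = northernmost).
#' @return data.frame with `lon`, `lat` of the cell centers.
#' @export
cell_center <- function(r, row, col) {
  stopifnot(inherits(r, "raster_grid"))
  cs <- r$cell_size_deg
  data.frame(lon = r$origin_lon + (col - 0.5) * cs,
             lat = r$origin_lat - (row - 0.5) * cs)
}

#' Locate points on the grid
#'
#' @param r a `raster_grid`.
#' @param lon,lat point coordinates, decimal degrees.
#' @return data.frame with `row`, `col` (NA when outside the grid extent).
#' @export
cell_from_lonlat <- function(r, lon, lat) {
  stopifnot(inherits(r, "raster_grid"))
  cs <- r$cell_size_deg
  col <- floor((lon - r$origin_lon) / cs) + 1L
  row <- floor((r$origin_lat - lat) / cs) + 1L
  bad <- row < 1L | row > nrow(r$values) | col < 1L | col > ncol(r$values) |
    !is.finite(lon) | !is.finite(lat)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Check that two grids share dimensions and geotransform
#' @param a,b `raster_grid` objects.
#' @return TRUE invisibly; error if misaligned.
#' @export
check_aligned <- function(a, b) {
  stopifnot(inherits(a, "raster_grid"), inherits(b, "raster_grid"))
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$origin_lon - b$origin_lon) > 1e-9 ||
      abs(a$origin_lat - b$origin_lat) > 1e-9 ||
      abs(a$cell_size_deg - b$cell_size_deg) > 1e-9)
    stop("raster grids are not aligned (dimensions or geotransform differ)",
         call. = FALSE)
  invisible(TRUE)
}

# replace values, keep geometry
set_values <- function(r, values) {
  r$values <- values
  r
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster with the standard 6-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`).
#' Round-trips values, mask and geotransform through [read_raster()].
#'
#' @param r a `raster_grid`.
#' @param path output file path.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "raster_grid"))
  v <- r$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$origin_lon),
    sprintf("yllcorner %.10g", r$origin_lat - nrow(v) * r$cell_size_deg),
    sprintf("cellsize %.10g", r$cell_size_deg),
    "NODATA_value -9999")
  body <- apply(v, 1L, function(row) {
    row[!is.finite(row)] <- -9999
    paste(formatC(row, format = "g", digits = 17), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path path to a `.asc` file written by [write_raster()] or any
#'   conforming tool.
#' @return a `raster_grid`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("not an ASCII grid: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys)) stop("ASCII grid header incomplete: ", path, call. = FALSE)
  nr <- as.integer(vals["nrows"]); nc <- as.integer(vals["ncols"])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc)
    stop("ASCII grid body has wrong cell count: ", path, call. = FALSE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA_real_
  raster_grid(m,
              origin_lon = vals["xllcorner"],
              origin_lat = vals["yllcorner"] + nr * vals["cellsize"],
              cell_size_deg = vals["cellsize"])
}

#' Write / read a named stack of aligned rasters
#'
#' One `.asc` file per layer, named `<prefix><layer>.asc`.
#'
#' @param stack named list of aligned `raster_grid`s.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (e.g. `"month06_"`).
#' @export
write_stack <- function(stack, dir, prefix = "") {
  stopifnot(is.list(stack), !is.null(names(stack)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(stack))
    write_raster(stack[[nm]], file.path(dir, paste0(prefix, nm, ".asc")))
  invisible(dir)
}

#' @rdname write_stack
#' @param layer_names layer names to read.
#' @export
read_stack <- function(dir, layer_names, prefix = "") {
  stack <- lapply(layer_names, function(nm)
    read_raster(file.path(dir, paste0(prefix, nm, ".asc"))))
  names(stack) <- layer_names
  for (nm in layer_names[-1]) check_aligned(stack[[1L]], stack[[nm]])
  stack
}
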