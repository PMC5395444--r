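#' Read an ESRI ASCII raster
#'
#' Parses the 6-line-header ESRI ASCII grid dialect (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`, then values
#' row-major from the northern edge). By default the result is a
#' [SuitabilityGrid-class] and values are checked to lie in \[0, 1\]; pass
#' `class = "RasterGrid"` for unconstrained rasters such as climate
#' covariates or district-ID grids.
#'
#' @param path path to the `.asc` file.
#' @param class `"SuitabilityGrid"` (default) or `"RasterGrid"`.
#' @return a grid object; nodata cells are `NA` in `values`.
#' @export
readGrid <- function(path, class = c("SuitabilityGrid", "RasterGrid")) {
  class <- match.arg(class)
  if (!file.exists(path))
    .stop2("io_error", "grid file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7)
    .stop2("format_error", "truncated ESRI ASCII grid: %s", path)
  hdr <- list()
  for (i in 1:6) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) != 2)
      .stop2("format_error", "malformed header line %d in %s", i, path)
    hdr[[tolower(tok[1])]] <- tok[2]
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    .stop2("format_error", "header missing %s in %s",
           paste(miss, collapse = ", "), path)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  nodata <- as.numeric(hdr$nodata_value)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nrows * ncols)
    .stop2("format_error", "expected %d values, found %d in %s",
           nrows * ncols, length(vals), path)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA
  if (class == "SuitabilityGrid" && any(m < 0 | m > 1, na.rm = TRUE))
    .stop2("range_error", "suitability values outside [0, 1] in %s", path)
  new(class, values = m, xll = as.numeric(hdr$xllcorner),
      yll = as.numeric(hdr$yllcorner), cellsize = as.numeric(hdr$cellsize),
      nodata = nodata)
}

#' Write an ESRI ASCII raster
#'
#' Inverse of [readGrid()]: round-trips losslessly at the stated precision.
#'
#' @param grid a [RasterGrid-class] (or subclass).
#' @param path output path.
#' @param digits significant digits written for cell values.
#' @return `path`, invisibly.
#' @export
writeGrid <- function(grid, path, digits = 10) {
  m <- grid@values
  m[is.na(m)] <- grid@nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(grid@xll, digits = 15)),
           paste("yllcorner", format(grid@yll, digits = 15)),
           paste("cellsize", format(grid@cellsize, digits = 15)),
           paste("NODATA_value", format(grid@nodata, digits = 15)))
  rows <- apply(m, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Construct a grid in memory
#'
#' @param values numeric matrix, row 1 = northern edge; `NA` = nodata.
#' @param xll,yll lower-left corner (degrees).
#' @param cellsize cell edge (degrees).
#' @param nodata sentinel used on file output.
#' @param class `"SuitabilityGrid"` (values checked against \[0, 1\]) or
#'   `"RasterGrid"`.
#' @return a grid object.
#' @export
makeGrid <- function(values, xll = 0, yll = 0, cellsize = 1, nodata = -9999,
                     class = c("SuitabilityGrid", "RasterGrid")) {
  class <- match.arg(class)
  new(class, values = values, xll = xll, yll = yll, cellsize = cellsize,
      nodata = nodata)
}

#' @describeIn makeGrid the value matrix of a grid.
#' @param grid a grid object.
#' @export
gridValues <- function(grid) grid@values

#' Max-normalize a suitability grid
#'
#' Rescales so the maximum species distribution probability is exactly one:
#' values are divided by the grid maximum over non-nodata cells. An all-zero
#' grid is returned unchanged with a warning (nothing to rescale); an
#' all-nodata grid is a degenerate input and raises an error. The operation
#' is idempotent.
#'
#' @param grid a [SuitabilityGrid-class] (or any [RasterGrid-class] with
#'   nonnegative values).
#' @return a [SuitabilityGrid-class] with maximum 1.
#' @export
normalizeGrid <- function(grid) {
  v <- grid@values
  if (all(is.na(v)))
    .stop2("degenerate_input_error", "all-nodata grid cannot be normalized")
  mx <- max(v, na.rm = TRUE)
  if (mx == 0) {
    warning("all-zero suitability grid: returned unchanged")
    return(makeGrid(v, grid@xll, grid@yll, grid@cellsize, grid@nodata))
  }
  makeGrid(v / mx, grid@xll, grid@yll, grid@cellsize, grid@nodata)
}

# row/col of the cell containing a point, under the floor convention
# (half-open [x, x + cellsize) intervals); NULL if outside the extent
.cellAt <- function(grid, lat, lon) {
  nr <- nrow(grid@values); nc <- ncol(grid@values); cs <- grid@cellsize
  dx <- (lon - grid@xll) / cs
  dy <- (lat - grid@yll) / cs
  if (dx < 0 || dx >= nc || dy < 0 || dy >= nr) return(NULL)
  c(row = nr - floor(dy), col = floor(dx) + 1)
}

#' Species distribution probability at a point
#'
#' Value of the grid cell containing the point (nearest cell under the floor
#' convention: the cell whose half-open `[x, x + cellsize)` interval contains
#' the coordinate; no interpolation). A nodata cell yields 0 with a
#' provenance attribute `note = "nodata"`.
#'
#' @param point a [geoPoint()].
#' @param grid a [SuitabilityGrid-class].
#' @return a number in \[0, 1\].
#' @export
sdpAt <- function(point, grid) {
  rc <- .cellAt(grid, point$lat, point$lon)
  if (is.null(rc))
    .stop2("out_of_extent_error",
           "point (%.4f, %.4f) outside the grid extent", point$lat, point$lon)
  v <- grid@values[rc["row"], rc["col"]]
  if (is.na(v)) return(structure(0, note = "nodata"))
  unname(v)
}

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("%s: %d x %d cells, cellsize %g, origin (%g, %g)\n",
              class(object), nrow(v), ncol(v), object@cellsize, object@xll,
              object@yll))
  cat(sprintf("  values: [%g, %g], %d nodata cell(s)\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})
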