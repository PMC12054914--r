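#' Raster grid geometry
#'
#' A `grid_spec` records the shared geometry that every raster layer in a run
#' must agree on: dimensions, square cell size in projected metres, the
#' lower-left corner of the grid, a CRS label and the nodata sentinel.
#' Rasters themselves are plain numeric matrices with `nrow(x) == nrows`,
#' row 1 being the northernmost row; nodata cells are held as `NA` in memory
#' and written out as the sentinel.
#'
#' @param nrows,ncols Grid dimensions (>= 1).
#' @param cellsize Cell edge length in metres (> 0).
#' @param origin_x,origin_y Projected coordinates (m) of the lower-left corner.
#' @param crs Free-text CRS identifier; layers are never reprojected, the
#'   label is carried through for bookkeeping only.
#' @param nodata Sentinel value used on disk for missing cells.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrows, ncols, cellsize,
                      origin_x = 0, origin_y = 0,
                      crs = "local-metric", nodata = -9999) {
  if (!is.numeric(nrows) || !is.numeric(ncols) || nrows < 1 || ncols < 1)
    stop("nrows and ncols must be >= 1")
  if (!is.numeric(cellsize) || cellsize <= 0)
    stop("cellsize must be > 0")
  structure(list(
    nrows = as.integer(nrows), ncols = as.integer(ncols),
    cellsize = as.numeric(cellsize),
    origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
    crs = as.character(crs), nodata = as.numeric(nodata)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.6g m cells, origin (%.6g, %.6g), crs '%s', nodata %g\n",
              x$nrows, x$ncols, x$cellsize, x$origin_x, x$origin_y, x$crs, x$nodata))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gm(%g,%g)", x$nrows, x$ncols, x$cellsize, x$origin_x, x$origin_y)
}

#' Test two grids for identity
#'
#' @param a,b `grid_spec` objects.
#' @return `TRUE` if geometry (dimensions, cell size, origin) matches.
#' @export
same_grid <- function(a, b) {
  isTRUE(all.equal(a$nrows, b$nrows)) && isTRUE(all.equal(a$ncols, b$ncols)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
}

# stop with a message naming both grids unless they match
check_aligned <- function(a, b, what = "rasters") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 format(a), format(b)))
  invisible(TRUE)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A `grid_spec`.
#' @return A list with matrices `x` and `y` (nrows x ncols) of projected
#'   cell-centre coordinates; row 1 is the northern edge.
#' @export
cell_centers <- function(grid) {
  cx <- grid$origin_x + (seq_len(grid$ncols) - 0.5) * grid$cellsize
  # row 1 = north: highest y
  cy <- grid$origin_y + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cellsize
  list(x = matrix(rep(cx, each = grid$nrows), grid$nrows, grid$ncols),
       y = matrix(rep(cy, times = grid$ncols), grid$nrows, grid$ncols))
}

#' Area of one grid cell in square metres
#' @param grid A `grid_spec`.
#' @return Cell area (m^2).
#' @export
cell_area_m2 <- function(grid) grid$cellsize^2

#' Write a raster as an ESRI ASCII grid
#'
#' Layers are stored in the plain-text Arc/Info ASCII grid dialect
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed by
#' rows north to south). Values are printed with 17 significant digits so a
#' write/read round trip reproduces doubles exactly.
#'
#' @param x Numeric matrix (`NA` = nodata).
#' @param grid A `grid_spec` matching `dim(x)`.
#' @param path Output file path (conventionally `.asc`).
#' @param units Optional units string recorded as a trailing comment line
#'   (ignored by readers of the format).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, grid, path, units = NULL) {
  if (!is.matrix(x) || nrow(x) != grid$nrows || ncol(x) != grid$ncols)
    stop("raster dimensions do not match grid_spec")
  vals <- x
  vals[is.na(vals)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.17g", grid$origin_x),
    sprintf("yllcorner %.17g", grid$origin_y),
    sprintf("cellsize %.17g", grid$cellsize),
    sprintf("NODATA_value %.17g", grid$nodata)
  ), con)
  for (i in seq_len(grid$nrows))
    writeLines(paste(sprintf("%.17g", vals[i, ]), collapse = " "), con)
  if (!is.null(units)) writeLines(sprintf("# units: %s", units), con)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path File written by [write_raster()] (or any ASCII-grid file).
#' @param crs CRS label to attach to the returned `grid_spec`.
#' @return A list with `values` (numeric matrix, nodata as `NA`) and
#'   `grid` (a `grid_spec`).
#' @export
read_raster <- function(path, crs = "local-metric") {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nr <- hdr$nrows; nc <- hdr$ncols
  body <- lines[i:length(lines)]
  body <- body[!grepl("^#", body) & nzchar(trimws(body))]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  grid <- grid_spec(nr, nc, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
                    crs = crs, nodata = hdr$nodata_value)
  list(values = m, grid = grid)
}

#' Align a raster from one grid to another
#'
#' Nearest-neighbour or bilinear resampling by cell-centre lookup. Categorical
#' layers must use `"nearest"` so no class codes are invented.
#'
#' @param x Numeric matrix on `src`.
#' @param src,dst `grid_spec` of the input and the target geometry. Extents
#'   must overlap; target cells falling outside `src` become `NA`.
#' @param method `"nearest"` or `"bilinear"`.
#' @param categorical Set `TRUE` for class-code layers; then `"bilinear"` is
#'   refused.
#' @return Numeric matrix on `dst`.
#' @export
align_resample <- function(x, src, dst, method = c("nearest", "bilinear"),
                           categorical = FALSE) {
  method <- match.arg(method)
  if (categorical && method == "bilinear")
    stop("bilinear resampling is not valid for categorical layers")
  if (same_grid(src, dst)) return(x)
  ctr <- cell_centers(dst)
  # fractional source index (1-based, row 1 = north)
  fx <- (ctr$x - src$origin_x) / src$cellsize + 0.5
  fy <- src$nrows - (ctr$y - src$origin_y) / src$cellsize + 0.5
  out <- matrix(NA_real_, dst$nrows, dst$ncols)
  if (method == "nearest") {
    ri <- round(fy); ci <- round(fx)
    ok <- ri >= 1 & ri <= src$nrows & ci >= 1 & ci <= src$ncols
    out[ok] <- x[cbind(ri[ok], ci[ok])]
  } else {
    fx <- as.vector(fx); fy <- as.vector(fy)
    r0 <- floor(fy); c0 <- floor(fx)
    tr <- fy - r0; tc <- fx - c0
    r1 <- pmin(pmax(r0 + 1, 1), src$nrows); r0 <- pmin(pmax(r0, 1), src$nrows)
    c1 <- pmin(pmax(c0 + 1, 1), src$ncols); c0 <- pmin(pmax(c0, 1), src$ncols)
    ok <- fy >= 0.5 & fy <= src$nrows + 0.5 & fx >= 0.5 & fx <= src$ncols + 0.5
    v00 <- x[cbind(r0, c0)]; v01 <- x[cbind(r0, c1)]
    v10 <- x[cbind(r1, c0)]; v11 <- x[cbind(r1, c1)]
    v <- (1 - tr) * ((1 - tc) * v00 + tc * v01) + tr * ((1 - tc) * v10 + tc * v11)
    out[ok] <- v[ok]
  }
  out
}
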