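#' Create a single-band georeferenced raster
#'
#' A `wq_raster` is a rectangular grid of values with a planar (projected,
#' metre-based) geotransform. The grid is north-up: row 1 is the northernmost
#' row, and the origin is the *top-left corner* of the grid. Missing cells are
#' stored as `NA` and written to disk using the `nodata` sentinel.
#'
#' The cell-center coordinate of the cell in row `r`, column `c` (1-based) is
#' `x = origin_x + (c - 0.5) * cell_size`,
#' `y = origin_y - (r - 0.5) * cell_size`.
#' This mapping is implemented once, in [cell_centers()] and [point_cell()],
#' and is bit-reproducible.
#'
#' @param values numeric matrix (rows = north to south); `NA` marks nodata.
#' @param origin numeric length-2: x and y of the grid's top-left corner, in
#'   planar metres.
#' @param cell_size positive cell edge length in metres (square cells).
#' @param nodata sentinel value used on disk for `NA` cells.
#' @param units free-text unit label for the values (e.g. `"mg/L"`).
#' @return An object of class `"wq_raster"`.
#' @examples
#' r <- wq_raster(matrix(1:12, 3, 4), origin = c(0, 30), cell_size = 10)
#' cell_centers(r)[1, 1, ]
#' @export
wq_raster <- function(values, origin = c(0, nrow(values)), cell_size = 1,
                      nodata = -9999, units = "") {
  values <- as.matrix(values)
  if (!is.numeric(values) && !is.logical(values))
    stop("raster values must be numeric or logical")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must be non-empty")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("origin must be two finite planar coordinates (metres)")
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), nodata = nodata,
         units = as.character(units)),
    class = "wq_raster")
}

#' @export
print.wq_raster <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<wq_raster> %d x %d cells, cell size %g m\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  origin (top-left): (%g, %g)\n", x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g]%s, %d NA\n", rng[1], rng[2],
              if (nzchar(x$units)) paste0(" ", x$units) else "",
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.wq_raster <- function(x) dim(x$values)

#' Cell-center coordinates of every cell
#'
#' @param raster a [wq_raster].
#' @return A `nrow x ncol x 2` array; `[, , 1]` holds x, `[, , 2]` holds y.
#' @export
cell_centers <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  xs <- raster$origin[1] + (seq_len(nc) - 0.5) * raster$cell_size
  ys <- raster$origin[2] - (seq_len(nr) - 0.5) * raster$cell_size
  out <- array(NA_real_, c(nr, nc, 2L))
  out[, , 1L] <- matrix(xs, nr, nc, byrow = TRUE)
  out[, , 2L] <- matrix(ys, nr, nc)
  out
}

#' Map planar coordinates to the containing cell
#'
#' Inverse of the cell-center mapping: each point is assigned the cell whose
#' extent contains it (equivalently, the nearest cell center). Points outside
#' the raster extent get `NA` indices.
#'
#' @param raster a [wq_raster].
#' @param x,y numeric coordinate vectors (planar metres).
#' @return data.frame with integer columns `row`, `col` (1-based).
#' @export
point_cell <- function(raster, x, y) {
  col <- floor((x - raster$origin[1]) / raster$cell_size) + 1L
  row <- floor((raster$origin[2] - y) / raster$cell_size) + 1L
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1L | col > ncol(raster$values) | row < 1L | row > nrow(raster$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Sample raster values at point locations
#'
#' Uses containing-cell (nearest cell center) sampling, matching the per-pixel
#' convention used for virtual-sensor retrieval; no interpolation is applied.
#'
#' @inheritParams point_cell
#' @return numeric vector; `NA` for points outside the extent or on nodata.
#' @export
raster_sample <- function(raster, x, y) {
  rc <- point_cell(raster, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- raster$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Read / write a raster as an Arc/Info ASCII grid
#'
#' Plain-text `.asc` grids carry the full geotransform (lower-left corner,
#' cell size, nodata). Values are written with 17 significant digits, so a
#' write/read round trip preserves float64 payloads bit-exactly. Only square
#' cells are supported; grids must be in a projected, metre-based CRS (this
#' package never reprojects -- reproject upstream if needed).
#'
#' @param path file path.
#' @param units unit label to attach on read (not stored in the file).
#' @return `read_asc` returns a [wq_raster]; `write_asc` invisibly returns
#'   `path`.
#' @export
read_asc <- function(path, units = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ASCII grid (missing ", paste(setdiff(need, names(hdr)), collapse = ", "), "): ", path)
  if (is.null(hdr$xllcorner)) hdr$xllcorner <- 0
  if (is.null(hdr$yllcorner)) hdr$yllcorner <- 0
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid payload has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  wq_raster(m, origin = origin, cell_size = hdr$cellsize, nodata = nodata,
            units = units)
}

#' @rdname read_asc
#' @param raster a [wq_raster] to write.
#' @export
write_asc <- function(raster, path) {
  stopifnot(inherits(raster, "wq_raster"))
  v <- raster$values
  if (is.logical(v)) v <- v + 0
  v[is.na(v)] <- raster$nodata
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %s", formatC(raster$origin[1], format = "g", digits = 17)),
    sprintf("yllcorner %s", formatC(raster$origin[2] - nr * raster$cell_size,
                                    format = "g", digits = 17)),
    sprintf("cellsize %s", formatC(raster$cell_size, format = "g", digits = 17)),
    sprintf("NODATA_value %s", formatC(raster$nodata, format = "g", digits = 17)))
  body <- apply(v, 1, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Assemble co-registered bands into a multispectral scene
#'
#' All bands must share shape, geotransform and nodata sentinel; the scene is
#' the unit of imagery consumed by [compute_ndwi()] and the retrieval
#' functions.
#'
#' @param bands named list of [wq_raster] objects (e.g. `"green"`, `"nir"`).
#' @return object of class `"ms_scene"` (a validated named list).
#' @export
ms_scene <- function(bands) {
  if (!is.list(bands) || length(bands) == 0L || is.null(names(bands)) ||
      any(!nzchar(names(bands))))
    stop("bands must be a non-empty named list of rasters")
  if (anyDuplicated(names(bands))) stop("duplicate band names")
  ref <- bands[[1]]
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!inherits(b, "wq_raster")) stop("band '", nm, "' is not a wq_raster")
    if (!identical(dim(b$values), dim(ref$values)) ||
        !isTRUE(all.equal(b$origin, ref$origin)) ||
        b$cell_size != ref$cell_size)
      stop("band '", nm, "' is not co-registered with band '",
           names(bands)[1], "' (shape/transform mismatch)")
  }
  structure(bands, class = "ms_scene")
}

#' @export
print.ms_scene <- function(x, ...) {
  cat(sprintf("<ms_scene> %d bands [%s], %d x %d cells\n", length(x),
              paste(names(x), collapse = ", "),
              nrow(x[[1]]$values), ncol(x[[1]]$values)))
  invisible(x)
}

#' Read a scene from a directory of ASCII grids
#'
#' Expects files `<band>.asc` for each requested band name.
#'
#' @param dir directory containing one `.asc` file per band.
#' @param bands character vector of band names to load.
#' @export
read_scene <- function(dir, bands) {
  paths <- file.path(dir, paste0(bands, ".asc"))
  missing <- bands[!file.exists(paths)]
  if (length(missing))
    stop("missing band files: ", paste(missing, collapse = ", "))
  ms_scene(stats::setNames(lapply(paths, read_asc), bands))
}
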