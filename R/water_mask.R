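#' Normalized difference water index
#'
#' NDWI = (green - NIR) / (green + NIR), computed per pixel. Open water
#' reflects strongly in the green band and absorbs in the near infrared, so
#' NDWI is positive over water and negative over most land and vegetation.
#' Cells where either band is nodata, or where the denominator is zero, are
#' nodata in the output.
#'
#' @param scene an [ms_scene] containing bands `green` and `nir` (names
#'   configurable).
#' @param green,nir band names to use.
#' @return a [wq_raster] of NDWI values (dimensionless, in `[-1, 1]` wherever
#'   both reflectances are positive).
#' @export
compute_ndwi <- function(scene, green = "green", nir = "nir") {
  stopifnot(inherits(scene, "ms_scene"))
  for (b in c(green, nir))
    if (!b %in% names(scene)) stop("scene is missing band '", b, "'")
  g <- scene[[green]]$values
  n <- scene[[nir]]$values
  den <- g + n
  out <- (g - n) / den
  out[!is.finite(out)] <- NA_real_
  out[den == 0] <- NA_real_
  ref <- scene[[green]]
  wq_raster(out, origin = ref$origin, cell_size = ref$cell_size,
            nodata = ref$nodata, units = "")
}

#' Threshold NDWI into a binary water mask
#'
#' The mask defines the estimation domain: concentration fields are only
#' estimated on water cells. The comparison is a strict `>`; nodata NDWI
#' cells are never water. The conventional threshold for open water is 0.
#' Optionally, connected components (4-neighbour) smaller than
#' `min_component` cells are removed to despeckle real imagery.
#'
#' @param ndwi a [wq_raster] of NDWI values.
#' @param threshold water cut-off; cells with `ndwi > threshold` are water.
#' @param min_component minimum connected-component size kept (1 = no
#'   cleanup).
#' @return a [wq_raster] of logical values with attribute `threshold`.
#' @export
threshold_water <- function(ndwi, threshold = 0, min_component = 1L) {
  stopifnot(inherits(ndwi, "wq_raster"))
  m <- !is.na(ndwi$values) & ndwi$values > threshold
  if (min_component > 1L) m <- drop_small_components(m, min_component)
  out <- wq_raster(m, origin = ndwi$origin, cell_size = ndwi$cell_size,
                   nodata = ndwi$nodata, units = "")
  attr(out, "threshold") <- threshold
  out
}

# label 4-connected components with a flood fill and drop the small ones
drop_small_components <- function(m, min_size) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(m & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    cells <- integer(0)
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[i] != 0L || !m[i]) next
      lab[i] <- cur
      cells <- c(cells, i)
      r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
      if (r > 1L) stack <- c(stack, i - 1L)
      if (r < nr) stack <- c(stack, i + 1L)
      if (c > 1L) stack <- c(stack, i - nr)
      if (c < nc) stack <- c(stack, i + nr)
    }
    if (length(cells) < min_size) m[cells] <- FALSE
  }
  m
}

#' Coordinates of all water cells
#'
#' @param mask logical [wq_raster] from [threshold_water()] (or any logical
#'   raster).
#' @return data.frame `row`, `col`, `x`, `y` of cell centers where the mask
#'   is `TRUE`.
#' @export
water_cells <- function(mask) {
  idx <- which(mask$values == TRUE, arr.ind = TRUE)
  data.frame(
    row = idx[, 1], col = idx[, 2],
    x = mask$origin[1] + (idx[, 2] - 0.5) * mask$cell_size,
    y = mask$origin[2] - (idx[, 1] - 0.5) * mask$cell_size)
}
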