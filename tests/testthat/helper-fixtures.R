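# small in-code fixtures shared across test files

# raster with values 1..(nr*nc) filled by row, cell size 1, origin (0, nr)
toy_raster <- function(nr = 3, nc = 3, cell = 1) {
  wq_raster(matrix(seq_len(nr * nc), nr, nc, byrow = TRUE),
            origin = c(0, nr * cell), cell_size = cell)
}

# two-band scene with constant green/nir values
toy_scene <- function(green, nir, nr = 2, nc = 2) {
  ms_scene(list(
    green = wq_raster(matrix(green, nr, nc), origin = c(0, nr), cell_size = 1),
    nir = wq_raster(matrix(nir, nr, nc), origin = c(0, nr), cell_size = 1)))
}

all_water_mask <- function(nr = 10, nc = 10, cell = 1) {
  wq_raster(matrix(TRUE, nr, nc), origin = c(0, nr * cell), cell_size = cell)
}

# random stations with values from a supplied field function
random_stations <- function(n, f = function(x, y) rnorm(length(x)),
                            xlim = c(0, 100), ylim = c(0, 100)) {
  x <- runif(n, xlim[1], xlim[2]); y <- runif(n, ylim[1], ylim[2])
  station_set(data.frame(id = seq_len(n), x = x, y = y, value = f(x, y)))
}

# independent reference entropy machinery used as the brute-force oracle:
# computed directly from definitions with base::table, no shared code paths
oracle_bin <- function(v, edges) {
  b <- findInterval(v, edges, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}
oracle_H <- function(...) {
  key <- do.call(paste, c(list(...), sep = "|"))
  p <- as.numeric(table(key)) / length(key)
  -sum(p * log(p))
}
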