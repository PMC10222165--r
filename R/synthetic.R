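#' Simulate a Gaussian random field raster
#'
#' Draws a zero-mean stationary Gaussian field with the covariance implied by
#' a variogram model (`cov(h) = psill * rho(h)`, plus a nugget as white
#' noise), with optional geometric anisotropy: the `range` applies along the
#' major axis at `angle` degrees (counter-clockwise from east) and
#' `range / anisotropy` across it. Two exact samplers are used: a Kronecker
#' factorization when the covariance is separable in the grid axes
#' (gaussian family with axis-aligned anisotropy), which scales to large
#' grids, and dense Cholesky factorization of the full covariance otherwise
#' (limited to grids of at most `dense_limit` cells). The result is
#' optionally recentered to `mean` and, if `sd` is given, rescaled to that
#' standard deviation; with `sd = NULL` the natural scale (variance = nugget
#' + partial sill) is kept.
#'
#' @param nrow,ncol grid size.
#' @param model a [variogram_model()] giving family, nugget, partial sill
#'   and range (in metres).
#' @param anisotropy ratio of major to minor correlation length (>= 1).
#' @param angle major-axis direction, degrees counter-clockwise from east.
#' @param cell_size,origin grid geometry (see [wq_raster()]).
#' @param mean,sd target moments; `sd = NULL` keeps the natural scale.
#' @param n_fields number of independent replicate fields to draw.
#' @param seed RNG seed; the same seed reproduces the draw bit-identically.
#' @param dense_limit cell cap for the dense sampler.
#' @return a [wq_raster] (or a list of them when `n_fields > 1`).
#' @export
simulate_gaussian_field <- function(nrow, ncol, model, anisotropy = 1,
                                    angle = 0, cell_size = 1,
                                    origin = c(0, nrow * cell_size),
                                    mean = 0, sd = NULL, n_fields = 1,
                                    seed = 1L, dense_limit = 4096) {
  stopifnot(inherits(model, "variogram_model"), anisotropy >= 1)
  set.seed(seed)
  nr <- as.integer(nrow); nc <- as.integer(ncol)
  r_major <- model$range
  r_minor <- model$range / anisotropy
  separable <- model$family == "gaussian" && (angle %% 90 == 0)
  draws <- vector("list", n_fields)
  if (separable) {
    rot90 <- (angle %% 180) == 90
    rx <- if (rot90) r_minor else r_major
    ry <- if (rot90) r_major else r_minor
    cx <- (seq_len(nc) - 0.5) * cell_size
    cy <- (seq_len(nr) - 0.5) * cell_size
    Cc <- exp(-(outer(cx, cx, "-") / rx)^2)
    Cr <- exp(-(outer(cy, cy, "-") / ry)^2)
    Lc <- chol_psd(Cc); Lr <- chol_psd(Cr)
    for (f in seq_len(n_fields)) {
      z <- matrix(stats::rnorm(nr * nc), nr, nc)
      smooth <- sqrt(model$psill) * (Lr %*% z %*% t(Lc))
      draws[[f]] <- smooth +
        if (model$nugget > 0)
          matrix(stats::rnorm(nr * nc, sd = sqrt(model$nugget)), nr, nc)
        else 0
    }
  } else {
    if (nr * nc > dense_limit)
      stop("grid of ", nr * nc, " cells exceeds the dense-sampler limit (",
           dense_limit, "); use the separable gaussian family or a coarser grid")
    xs <- rep((seq_len(nc) - 0.5) * cell_size, each = nr)
    ys <- rep((nr - seq_len(nr) + 0.5) * cell_size, times = nc)  # north-up rows
    a <- angle * pi / 180
    u <- (outer(xs, xs, "-")) * cos(a) + (outer(ys, ys, "-")) * sin(a)
    v <- -(outer(xs, xs, "-")) * sin(a) + (outer(ys, ys, "-")) * cos(a)
    h <- sqrt((u / r_major)^2 + (v / r_minor)^2)
    rho <- switch(model$family,
                  spherical = ifelse(h >= 1, 0, 1 - 1.5 * h + 0.5 * h^3),
                  exponential = exp(-h),
                  gaussian = exp(-h^2))
    C <- model$psill * rho
    L <- chol_psd(C)
    for (f in seq_len(n_fields)) {
      vals <- drop(L %*% stats::rnorm(nr * nc)) +
        stats::rnorm(nr * nc, sd = sqrt(model$nugget))
      draws[[f]] <- matrix(vals, nr, nc)    # column-filled, matches xs/ys order
    }
  }
  out <- lapply(draws, function(m) {
    if (!is.null(sd)) {
      s <- stats::sd(as.vector(m))
      if (s > 0) m <- m * (sd / s)
    }
    m <- m - base::mean(m) + mean
    wq_raster(m, origin = origin, cell_size = cell_size, units = "mg/L")
  })
  if (n_fields == 1) out[[1]] else out
}

# lower Cholesky factor with a jitter escalation for numerically PSD matrices
chol_psd <- function(C) {
  jit <- 0
  base_ <- base::mean(diag(C))
  for (k in 0:8) {
    res <- tryCatch(t(chol(C + diag(jit, nrow(C)))), error = function(e) NULL)
    if (!is.null(res)) return(res)
    jit <- base_ * 10^(-12 + 2 * k)
  }
  stop("covariance matrix is not positive semi-definite even after jitter")
}

#' Synthetic lake mask
#'
#' An irregular elliptical lake: the ellipse inscribed in the grid, with its
#' boundary perturbed by a seeded low-frequency sinusoid so arms and bays
#' appear. Deterministic given the seed.
#'
#' @param nrow,ncol,cell_size,origin grid geometry.
#' @param coverage approximate fraction of the grid that is water.
#' @param irregularity amplitude of the boundary perturbation (0 = ellipse).
#' @param seed RNG seed.
#' @return logical [wq_raster].
#' @export
synthetic_lake_mask <- function(nrow, ncol, cell_size = 1,
                                origin = c(0, nrow * cell_size),
                                coverage = 0.6, irregularity = 0.25,
                                seed = 1L) {
  set.seed(seed)
  nr <- nrow; nc <- ncol
  cx <- nc / 2; cy <- nr / 2
  phase <- stats::runif(3, 0, 2 * pi)
  ampl <- stats::runif(3, 0.3, 1) * irregularity
  r <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dx <- (j - 0.5 - cx) / (nc / 2); dy <- (i - 0.5 - cy) / (nr / 2)
    th <- atan2(dy, dx)
    lim <- sqrt(coverage) * (1 + ampl[1] * sin(2 * th + phase[1]) +
                               ampl[2] * sin(3 * th + phase[2]) +
                               ampl[3] * sin(5 * th + phase[3]))
    r[i, j] <- sqrt(dx^2 + dy^2) < lim
  }
  wq_raster(r == 1, origin = origin, cell_size = cell_size)
}

#' Sample noisy stations from a truth field
#'
#' Places `n` stations on distinct water cells, either uniformly at random or
#' clustered around a few attraction centers (emulating the realistic case
#' of stations concentrated near shores and river mouths), and observes
#' `value = truth + N(0, noise_sd^2)` at each cell center.
#'
#' @param truth [wq_raster] ground-truth field.
#' @param mask logical [wq_raster] water mask (same grid).
#' @param n number of stations (at most the number of water cells).
#' @param noise_sd measurement noise standard deviation (mg/L).
#' @param seed RNG seed.
#' @param layout `"random"` or `"clustered"`.
#' @param n_clusters number of attraction centers for the clustered layout.
#' @return [station_set] with `source = "monitoring"`.
#' @export
sample_stations <- function(truth, mask, n, noise_sd = 0.3, seed = 1L,
                            layout = c("random", "clustered"),
                            n_clusters = 3) {
  layout <- match.arg(layout)
  set.seed(seed)
  wc <- water_cells(mask)
  if (nrow(wc) == 0) stop("mask has no water cells")
  if (n > nrow(wc)) stop("n exceeds the number of water cells (", nrow(wc), ")")
  if (layout == "random") {
    pick <- sample.int(nrow(wc), n)
  } else {
    centers <- wc[sample.int(nrow(wc), min(n_clusters, nrow(wc))), ]
    dmin <- Reduce(pmin, lapply(seq_len(nrow(centers)), function(k)
      sqrt((wc$x - centers$x[k])^2 + (wc$y - centers$y[k])^2)))
    scale_ <- max(dmin) / 3 + 1e-9
    pick <- sample.int(nrow(wc), n, prob = exp(-(dmin / scale_)^2) + 1e-9)
  }
  cells <- wc[pick, ]
  value <- truth$values[cbind(cells$row, cells$col)] +
    stats::rnorm(n, sd = noise_sd)
  station_set(data.frame(id = sprintf("M%d", seq_len(n)), x = cells$x,
                         y = cells$y, value = value, source = "monitoring"))
}

#' Synthetic multispectral scene linked to a truth field
#'
#' Builds `n_bands` co-registered bands. Each signal band is affine in the
#' truth plus its own spatially correlated nuisance component (emulating
#' band-specific atmospheric and bottom effects) plus white sensor noise:
#' `band = a + b * (truth + nuisance_b) + e`. Because every signal band
#' carries an independent nuisance, combining all of them averages the
#' nuisance away, so the full signal set is identifiably the best subset for
#' retrieval. The remaining decoy bands are pure noise at a similar
#' reflectance scale.
#'
#' @param truth [wq_raster] ground-truth concentration field.
#' @param n_bands total number of bands (>= 2); named from
#'   [default_bands()] then `b9`, `b10`, ...
#' @param signal_bands how many bands carry signal (>= 2 recommended).
#' @param link_coefficients optional `signal_bands x 2` matrix of `(a, b)`
#'   per signal band; defaults alternate signs of `b`.
#' @param nuisance_sd sd of each band's correlated nuisance, relative to the
#'   truth standard deviation (0 disables it).
#' @param noise_sd white reflectance noise standard deviation.
#' @param seed RNG seed.
#' @return an [ms_scene]; attribute `signal_bands` records the informative
#'   band names.
#' @export
make_synthetic_scene <- function(truth, n_bands = 6, signal_bands = 2,
                                 link_coefficients = NULL, nuisance_sd = 0.5,
                                 noise_sd = 0.01, seed = 1L) {
  if (n_bands < 2) stop("need at least 2 bands")
  signal_bands <- min(signal_bands, n_bands)
  set.seed(seed)
  nms <- c(default_bands(), sprintf("b%d", 9:20))[seq_len(n_bands)]
  tv <- truth$values
  sc <- stats::sd(as.vector(tv), na.rm = TRUE)
  if (!is.finite(sc) || sc == 0) sc <- 1
  # links are centered on the truth mean so reflectances stay positive
  if (is.null(link_coefficients))
    link_coefficients <- cbind(a = rep(0.2, signal_bands),
                               b = 0.05 / sc * (-1)^(seq_len(signal_bands) - 1))
  tv <- tv - base::mean(tv, na.rm = TRUE)
  nuis <- if (nuisance_sd > 0)
    simulate_gaussian_field(nrow(tv), ncol(tv),
                            variogram_model("gaussian", nugget = 0, psill = 1,
                                            range = truth$cell_size *
                                              max(nrow(tv), ncol(tv)) / 4),
                            cell_size = truth$cell_size, mean = 0,
                            sd = nuisance_sd * sc, n_fields = signal_bands,
                            seed = seed + 7L)
  else NULL
  if (!is.null(nuis) && signal_bands == 1) nuis <- list(nuis)
  set.seed(seed + 13L)
  bands <- vector("list", n_bands)
  for (b in seq_len(n_bands)) {
    base_ <- if (b <= signal_bands)
      link_coefficients[b, 1] + link_coefficients[b, 2] *
        (tv + if (is.null(nuis)) 0 else nuis[[b]]$values)
    else matrix(0.1, nrow(tv), ncol(tv))
    noise <- matrix(stats::rnorm(length(tv), sd = noise_sd), nrow(tv))
    bands[[b]] <- wq_raster(base_ + noise, origin = truth$origin,
                            cell_size = truth$cell_size, units = "reflectance")
  }
  out <- ms_scene(stats::setNames(bands, nms))
  attr(out, "signal_bands") <- nms[seq_len(signal_bands)]
  out
}

#' Synthetic covariate rasters
#'
#' `n_informative` covariates are affine in the truth plus noise (with known
#' coefficients), the rest are independent white noise, so dominant-covariate
#' selection and kernel steering have a known right answer.
#'
#' @param truth [wq_raster] ground-truth field.
#' @param names covariate names (defaults to the usual water-quality
#'   drivers).
#' @param n_informative how many of them are linked to the truth.
#' @param noise_sd noise added to informative covariates, relative to the
#'   truth standard deviation.
#' @param seed RNG seed.
#' @return named list of [wq_raster]s; attribute `informative` records the
#'   linked names.
#' @export
make_covariates <- function(truth, names = c("turbidity", "ph", "temperature",
                                             "oxygen", "precipitation",
                                             "wind"),
                            n_informative = 2, noise_sd = 0.1, seed = 1L) {
  if (length(names) < 1) stop("need at least one covariate")
  set.seed(seed)
  tv <- truth$values
  sc <- stats::sd(as.vector(tv), na.rm = TRUE)
  if (!is.finite(sc) || sc == 0) sc <- 1
  out <- lapply(seq_along(names), function(k) {
    vals <- if (k <= n_informative)
      (2 - k) + k * tv + matrix(stats::rnorm(length(tv), sd = noise_sd * sc),
                                nrow(tv))
    else matrix(stats::rnorm(length(tv), sd = sc), nrow(tv))
    wq_raster(vals, origin = truth$origin, cell_size = truth$cell_size)
  })
  out <- stats::setNames(out, names)
  attr(out, "informative") <- names[seq_len(min(n_informative, length(names)))]
  out
}

#' Generate a complete synthetic world
#'
#' One call produces everything the pipeline consumes with known ground
#' truth: an anisotropic concentration field (default around 9 mg/L with a
#' 2 mg/L spread, i.e. roughly the 5-13 mg/L span of eutrophic lake COD), an
#' irregular lake mask, a linked multispectral scene, covariates, and noisy
#' monitoring stations. Every component is a pure function of the
#' parameters and the seed.
#'
#' @param nrow,ncol,cell_size grid geometry.
#' @param model variogram model of the truth field.
#' @param anisotropy,angle field anisotropy (see
#'   [simulate_gaussian_field()]).
#' @param mean_value mean concentration (mg/L).
#' @param n_stations number of monitoring stations.
#' @param station_noise_sd measurement noise (mg/L).
#' @param layout station layout.
#' @param n_bands,signal_bands,band_noise_sd scene parameters.
#' @param covariates,n_informative covariate parameters.
#' @param coverage,irregularity mask parameters (`coverage = 1` gives an
#'   all-water mask).
#' @param seed master seed; sub-seeds are derived deterministically.
#' @return list of class `"synthetic_world"`: `truth`, `mask`, `scene`,
#'   `covariates`, `stations`, `params`.
#' @export
make_synthetic_world <- function(nrow = 60, ncol = 60, cell_size = 10,
                                 model = variogram_model("gaussian",
                                                         nugget = 0.05,
                                                         psill = 4,
                                                         range = 150),
                                 anisotropy = 3, angle = 0, mean_value = 9,
                                 n_stations = 14, station_noise_sd = 0.3,
                                 layout = "clustered", n_bands = 6,
                                 signal_bands = 2, band_noise_sd = 0.01,
                                 covariates = c("turbidity", "ph",
                                                "temperature", "oxygen"),
                                 n_informative = 2, coverage = 0.65,
                                 irregularity = 0.25, seed = 1L) {
  truth <- simulate_gaussian_field(nrow, ncol, model, anisotropy, angle,
                                   cell_size = cell_size, mean = mean_value,
                                   seed = seed)
  mask <- if (coverage >= 1)
    wq_raster(matrix(TRUE, nrow, ncol), origin = truth$origin,
              cell_size = cell_size)
  else synthetic_lake_mask(nrow, ncol, cell_size, coverage = coverage,
                           irregularity = irregularity, seed = seed + 1L)
  scene <- make_synthetic_scene(truth, n_bands, signal_bands,
                                noise_sd = band_noise_sd, seed = seed + 2L)
  covs <- make_covariates(truth, covariates, n_informative, seed = seed + 3L)
  stations <- sample_stations(truth, mask, n_stations, station_noise_sd,
                              seed = seed + 4L, layout = layout)
  for (cv in names(covs))
    stations[[cv]] <- raster_sample(covs[[cv]], stations$x, stations$y)
  structure(list(truth = truth, mask = mask, scene = scene,
                 covariates = covs, stations = stations,
                 params = list(model = model, anisotropy = anisotropy,
                               angle = angle, mean_value = mean_value,
                               n_stations = n_stations,
                               station_noise_sd = station_noise_sd,
                               signal_bands = attr(scene, "signal_bands"),
                               informative = attr(covs, "informative"),
                               seed = seed)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d grid, %d stations, seed %d\n",
              nrow(x$truth$values), ncol(x$truth$values),
              nrow(x$stations), x$params$seed))
  cat("  signal bands:", paste(x$params$signal_bands, collapse = ", "),
      "| informative covariates:",
      paste(x$params$informative, collapse = ", "), "\n")
  invisible(x)
}

#' Replicate-field realizations at candidate sites
#'
#' Draws `t` independent replicate fields from the same generating model and
#' samples them at the candidate locations, emulating the monthly record
#' that drives the entropy-based network design (each realization plays the
#' role of one month's retrieved value).
#'
#' @param sites data.frame with `x`, `y` candidate locations.
#' @param nrow,ncol,cell_size grid geometry the fields are drawn on.
#' @param model,anisotropy,angle,mean_value field parameters (see
#'   [simulate_gaussian_field()]).
#' @param t number of realizations (>= 2).
#' @param seed RNG seed.
#' @return numeric matrix, one row per site, one column per realization.
#' @export
candidate_realizations <- function(sites, nrow, ncol, model, anisotropy = 1,
                                   angle = 0, mean_value = 9, cell_size = 10,
                                   t = 12, seed = 1L) {
  if (t < 2) stop("need t >= 2 realizations")
  fields <- simulate_gaussian_field(nrow, ncol, model, anisotropy, angle,
                                    cell_size = cell_size, mean = mean_value,
                                    n_fields = t, seed = seed)
  vapply(fields, function(f) raster_sample(f, sites$x, sites$y),
         numeric(nrow(sites)))
}
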