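test_that("field simulation is a pure function of parameters and seed", {
  mod <- variogram_model("gaussian", nugget = 0.1, psill = 2, range = 8)
  a <- simulate_gaussian_field(15, 15, mod, anisotropy = 2, seed = 7)
  b <- simulate_gaussian_field(15, 15, mod, anisotropy = 2, seed = 7)
  expect_identical(a$values, b$values)
  c_ <- simulate_gaussian_field(15, 15, mod, anisotropy = 2, seed = 8)
  expect_false(identical(a$values, c_$values))
  # dense and separable samplers agree in law; check both run
  mods <- variogram_model("spherical", nugget = 0, psill = 1, range = 5)
  d <- simulate_gaussian_field(10, 10, mods, angle = 30, seed = 1)
  expect_equal(dim(d$values), c(10, 10))
  expect_error(simulate_gaussian_field(100, 100, mods, seed = 1),
               "dense-sampler limit")
})

test_that("sample variance over seeds matches nugget + partial sill", {
  mod <- variogram_model("gaussian", nugget = 0.3, psill = 1.2, range = 4)
  vars <- vapply(1:20, function(s)
    var(as.vector(simulate_gaussian_field(30, 30, mod, seed = s)$values)), 0)
  expect_equal(mean(vars), 1.5, tolerance = 0.2 * 1.5)
})

test_that("a short range collapses the variogram to pure nugget", {
  mod <- variogram_model("gaussian", nugget = 0, psill = 1, range = 0.05)
  f <- simulate_gaussian_field(25, 25, mod, seed = 5)
  wc <- water_cells(all_water_mask(25, 25))
  st <- station_set(data.frame(id = seq_len(nrow(wc)), x = wc$x, y = wc$y,
                               value = f$values[cbind(wc$row, wc$col)]))
  est <- empirical_variogram(st, n_bins = 6, max_lag = 12)
  pop <- est$count > 100
  expect_true(all(abs(est$gamma[pop] - 1) < 0.25))
})

test_that("anisotropic fields decorrelate faster across the minor axis", {
  mod <- variogram_model("gaussian", nugget = 0, psill = 1, range = 12)
  cx <- numeric(0); cy <- numeric(0)
  for (s in 1:5) {
    f <- simulate_gaussian_field(40, 40, mod, anisotropy = 4, angle = 0,
                                 seed = s)$values
    cx <- c(cx, cor(as.vector(f[, 1:35]), as.vector(f[, 6:40])))  # lag 5 in x
    cy <- c(cy, cor(as.vector(f[1:35, ]), as.vector(f[6:40, ])))  # lag 5 in y
  }
  expect_gt(mean(cx), mean(cy) + 0.2)
})

test_that("stations sit on water and reflect the truth plus noise", {
  w <- make_synthetic_world(nrow = 25, ncol = 25, n_stations = 14, seed = 13)
  expect_equal(nrow(w$stations), 14)
  on_water <- raster_sample(w$mask, w$stations$x, w$stations$y)
  expect_true(all(on_water == 1))
  # zero-noise draw equals the truth at the station cells
  st0 <- sample_stations(w$truth, w$mask, 10, noise_sd = 0, seed = 2)
  expect_equal(st0$value, raster_sample(w$truth, st0$x, st0$y))
  st0b <- sample_stations(w$truth, w$mask, 10, noise_sd = 0, seed = 2)
  expect_identical(st0$value, st0b$value)
  expect_error(sample_stations(w$truth, w$mask, 1e6, seed = 1), "exceeds")
})

test_that("scene bands carry signal where declared, noise elsewhere", {
  mod <- variogram_model("gaussian", nugget = 0.05, psill = 4, range = 60)
  truth <- simulate_gaussian_field(30, 30, mod, cell_size = 10, mean = 9,
                                   seed = 19)
  sc <- make_synthetic_scene(truth, n_bands = 5, signal_bands = 2,
                             nuisance_sd = 0, noise_sd = 0, seed = 19)
  expect_length(sc, 5)
  # zero noise + zero nuisance: signal band is exactly affine in the truth
  b1 <- as.vector(sc[[1]]$values); tv <- as.vector(truth$values)
  expect_equal(abs(cor(b1, tv)), 1, tolerance = 1e-12)
  # decoy bands are uncorrelated with the truth
  scn <- make_synthetic_scene(truth, n_bands = 5, signal_bands = 2,
                              nuisance_sd = 0, noise_sd = 0.01, seed = 19)
  decoy <- as.vector(scn[[5]]$values)
  expect_lt(abs(cor(decoy, tv)), 0.12)
})

test_that("informative covariates track the truth's gradients", {
  mod <- variogram_model("gaussian", nugget = 0, psill = 4, range = 80)
  truth <- simulate_gaussian_field(20, 20, mod, cell_size = 10, mean = 9,
                                   seed = 23)
  covs <- make_covariates(truth, c("turbidity", "ph", "wind"),
                          n_informative = 1, noise_sd = 0, seed = 23)
  expect_equal(attr(covs, "informative"), "turbidity")
  # zero-noise informative covariate is affine in the truth: gradients parallel
  expect_equal(cor(as.vector(covs$turbidity$values), as.vector(truth$values)),
               1, tolerance = 1e-12)
  # pure-noise covariates degrade steering gracefully to near-isotropic
  wc <- water_cells(all_water_mask(20, 20, 10))
  set.seed(1)
  idx <- sample(nrow(wc), 50)
  co <- cbind(wc$x[idx], wc$y[idx])
  z <- as.vector(covs$wind$values)[idx]      # white noise field
  gr <- pilot_gradients(co, z, sigma = 30, M = 15)
  st <- steering_matrices(co, gr, lambda = 5, M = 30)
  expect_lt(median(st$anisotropy), 1.1)
})

test_that("the synthetic world is reproducible end to end", {
  w1 <- make_synthetic_world(nrow = 20, ncol = 20, seed = 99)
  w2 <- make_synthetic_world(nrow = 20, ncol = 20, seed = 99)
  expect_identical(w1$truth$values, w2$truth$values)
  expect_identical(w1$stations$value, w2$stations$value)
  expect_identical(w1$scene$green$values, w2$scene$green$values)
  expect_identical(w1$mask$values, w2$mask$values)
})
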