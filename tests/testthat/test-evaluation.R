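test_that("metrics match hand-evaluated formulas", {
  m <- compute_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$r2, 0, tolerance = 1e-12)
  expect_equal(m$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m$m, 3)

  perfect <- compute_metrics(c(5, 9, 13), c(5, 9, 13))
  expect_equal(c(perfect$r2, perfect$mae, perfect$rmse), c(1, 0, 0))

  flat <- compute_metrics(c(2, 2), c(1, 3))
  expect_true(is.na(flat$r2))
  expect_equal(flat$mae, 1)
})

test_that("metrics are permutation-invariant and RMSE >= MAE always", {
  set.seed(51)
  for (i in 1:20) {
    y <- rnorm(15); e <- rnorm(15)
    m <- compute_metrics(y, e)
    perm <- sample(15)
    mp <- compute_metrics(y[perm], e[perm])
    expect_equal(m$rmse, mp$rmse)
    expect_equal(m$r2, mp$r2)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("LOOCV folds match a hand-computed mean predictor", {
  st <- station_set(data.frame(id = 1:3, x = c(0, 1, 2), y = 0,
                               value = c(0, 0, 3)))
  cv <- loocv(st, function(train, newdata) mean(train$value))
  expect_equal(cv$folds$predicted, c(1.5, 1.5, 0))
  expect_equal(cv$metrics$mae, 2)
  expect_error(loocv(st[1, ], function(a, b) 0), ">= 3")
})

test_that("virtual sensors stay on the training side of every fold", {
  st <- station_set(data.frame(id = 1:4, x = c(0, 1, 2, 3), y = 0,
                               value = c(1, 2, 3, 4)))
  virt <- station_set(data.frame(id = "v1", x = 9, y = 9, value = 100,
                                 source = "virtual"))
  seen <- new.env(); seen$n_train <- integer(0)
  cv <- loocv(st, function(train, newdata) {
    seen$n_train <- c(seen$n_train, nrow(train))
    expect_false(newdata$id %in% train$id)
    expect_true("v1" %in% train$id)
    mean(train$value)
  }, virtual = virt)
  expect_equal(nrow(cv$folds), 4)            # only monitoring stations held out
  expect_equal(seen$n_train, rep(4, 4))      # 3 training stations + 1 virtual
})

test_that("failed folds are excluded with a warning", {
  st <- station_set(data.frame(id = 1:4, x = 1:4, y = 0, value = c(1, 2, 3, 4)))
  expect_warning(
    cv <- loocv(st, function(train, newdata)
      if (newdata$id == 2) stop("boom") else mean(train$value)),
    "failed")
  expect_equal(cv$n_failed, 1)
  expect_equal(cv$metrics$m, 3)
})

test_that("IDW obeys its defining conventions", {
  one <- station_set(data.frame(id = 1, x = 0, y = 0, value = 5))
  expect_equal(idw_interpolate(one, data.frame(x = c(1, 50), y = c(2, 3))),
               c(5, 5))
  two <- station_set(data.frame(id = 1:2, x = c(-1, 1), y = 0,
                                value = c(2, 4)))
  expect_equal(idw_interpolate(two, data.frame(x = 0, y = 0)), 3)
  at <- station_set(data.frame(id = 1:2, x = c(0, 1), y = 0, value = c(7, 9)))
  expect_equal(idw_interpolate(at, data.frame(x = 0, y = 0)), 7)  # exactness
})

test_that("ordinary kriging is exact, unbiased, and rejects duplicates", {
  set.seed(61)
  st <- random_stations(15, function(x, y) sin(x / 20) + y / 100)
  mod <- variogram_model("spherical", nugget = 0, psill = 1, range = 50)
  # exact at a station with zero nugget
  expect_equal(ordinary_kriging(st, mod, st[3, c("x", "y")]), st$value[3],
               tolerance = 1e-8)
  # weights sum to 1 at arbitrary targets
  res <- ordinary_kriging(st, mod, data.frame(x = c(10, 55), y = c(80, 15)),
                          return_weights = TRUE)
  expect_equal(rowSums(res$weights), c(1, 1), tolerance = 1e-10)
  dup <- rbind(as.data.frame(st), data.frame(id = "dup", x = st$x[1],
                                             y = st$y[1], value = 1,
                                             source = "monitoring"))
  expect_error(ordinary_kriging(station_set(dup), mod, data.frame(x = 1, y = 1)),
               "duplicate")
})

test_that("kriging beats IDW on fields with known spherical structure", {
  mod <- variogram_model("spherical", nugget = 0.02, psill = 1, range = 10)
  wins <- 0
  for (seed in 1:10) {
    f <- simulate_gaussian_field(20, 20, mod, seed = seed + 300)
    mask <- all_water_mask(20, 20)
    st <- sample_stations(f, mask, 40, noise_sd = 0.05, seed = seed,
                          layout = "random")
    cv_ok <- loocv(st, function(train, newdata) {
      est <- empirical_variogram(train, n_bins = 8, max_lag = 14)
      ordinary_kriging(train, fit_variogram_model(est, "spherical"), newdata)
    })
    cv_idw <- loocv(st, function(train, newdata) idw_interpolate(train, newdata))
    if (cv_ok$metrics$mae <= cv_idw$metrics$mae) wins <- wins + 1
  }
  expect_gte(wins, 5)    # at least the median seed favours kriging
})

test_that("TSCH through the CV loop is near-exact on planar data", {
  set.seed(71)
  st <- random_stations(40, function(x, y) 1 + 0.02 * x - 0.01 * y,
                        xlim = c(0, 50), ylim = c(0, 50))
  cv <- loocv(st, function(train, newdata)
    predict(tsch(value ~ 1, train, order = 1, sigma = 10, steering = FALSE),
            newdata))
  expect_lt(cv$metrics$mae, 1e-6)
})

test_that("evaluate_methods runs all four methods on shared folds", {
  w <- make_synthetic_world(nrow = 30, ncol = 30, n_stations = 30,
                            coverage = 1, layout = "random", seed = 81)
  res <- evaluate_methods(w$stations, tsch_args = list(sigma = 100, order = 1))
  expect_named(res, c("tsch", "tsch_iso", "idw", "kriging"))
  for (m in res) expect_true(is.finite(m$metrics$mae))
})
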