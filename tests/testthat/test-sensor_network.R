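test_that("candidate grids have the expected counts and errors", {
  mask <- all_water_mask(100, 100, cell = 1)      # 100 m x 100 m
  cand <- generate_candidates(mask, spacing = 10)
  expect_equal(nrow(cand), 100)                   # 10 x 10 grid

  none <- wq_raster(matrix(FALSE, 5, 5), origin = c(0, 5), cell_size = 1)
  expect_error(generate_candidates(none, 1), "no candidate")

  single <- wq_raster(matrix(c(rep(FALSE, 12), TRUE, rep(FALSE, 12)), 5, 5),
                      origin = c(0, 5), cell_size = 1)
  c1 <- generate_candidates(single, spacing = 1)
  expect_equal(nrow(c1), 1)
  expect_equal(c(c1$x, c1$y), c(2.5, 2.5))        # that cell's center

  expect_error(generate_candidates(mask, spacing = 0.5), ">= cell size")
})

test_that("marginal entropy matches closed forms", {
  m4 <- entropy_model(rbind(c(1, 2, 3, 4)), n_bins = 4)
  expect_equal(marginal_entropy(m4, 1), log(4), tolerance = 1e-12)
  m1 <- entropy_model(rbind(c(5, 5, 5, 5.0)), n_bins = 4)
  expect_equal(marginal_entropy(m1, 1), 0)
  m2 <- entropy_model(rbind(c(0, 0, 1, 1)), n_bins = 2)
  expect_equal(marginal_entropy(m2, 1), log(2), tolerance = 1e-12)
})

test_that("joint and conditional entropies obey the information identities", {
  set.seed(21)
  a <- runif(400)
  m <- entropy_model(rbind(a, a, rep(0.5, 400), runif(400)), n_bins = 2)
  ea <- marginal_entropy(m, 1)
  expect_equal(joint_entropy(m, c(1, 2)), ea, tolerance = 1e-12)  # identical copy
  expect_equal(joint_entropy(m, c(1, 3)), ea, tolerance = 1e-12)  # constant partner
  expect_equal(conditional_entropy(m, 2, 1), 0, tolerance = 1e-12)
  expect_equal(conditional_entropy(m, 3, 4), 0, tolerance = 1e-12)
  # independence: E(A|B) ~ E(A), joint ~ ln 4 for 2x2 equiprobable bins
  expect_equal(joint_entropy(m, c(1, 4)), log(4), tolerance = 0.02)
  expect_equal(conditional_entropy(m, 1, 4), ea, tolerance = 0.02)
  # bounds: max(Ea, Eb) <= Eab <= Ea + Eb
  eb <- marginal_entropy(m, 4)
  eab <- joint_entropy(m, c(1, 4))
  expect_gte(eab + 1e-12, max(ea, eb))
  expect_lte(eab, ea + eb + 1e-12)
})

test_that("entropies are invariant to permuting the realization order", {
  set.seed(8)
  r <- matrix(runif(60), 3)
  m1 <- entropy_model(r, n_bins = 5)
  perm <- sample(ncol(r))
  m2 <- entropy_model(r[, perm], n_bins = 5)
  for (i in 1:3)
    expect_equal(marginal_entropy(m1, i), marginal_entropy(m2, i))
  expect_equal(joint_entropy(m1, c(1, 3)), joint_entropy(m2, c(1, 3)))
})

test_that("greedy selection starts at max entropy and shuns duplicates", {
  set.seed(31)
  base <- runif(200)
  pool <- rbind(
    site1 = 0.5 + 0.01 * runif(200),   # low entropy
    site2 = runif(200),                # high entropy
    site2dup = NA,                     # duplicate of site2, filled below
    site4 = runif(200, 0.2, 0.8))
  pool[3, ] <- pool[2, ]
  m <- entropy_model(pool, n_bins = 6)
  sel <- greedy_select(m, k_max = 3)
  expect_equal(sel$site[1], 2)               # highest marginal entropy
  expect_false(sel$site[2] == 3)             # verbatim duplicate never second
  expect_true(all(sel$score[-1] >= -1e-12))  # redundancy I >= 0
})

test_that("greedy selection agrees with a brute-force oracle on small pools", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(3:5, 1)
    pool <- matrix(runif(n * 50), n)
    nb <- 4
    m <- entropy_model(pool, n_bins = nb)
    sel <- greedy_select(m, k_max = min(3, n))

    # oracle: same sequential objective, computed from definitions
    edges <- seq(min(pool), max(pool), length.out = nb + 1)
    bins <- matrix(oracle_bin(pool, edges), nrow = n)
    H <- function(i) oracle_H(bins[i, ])
    Hj <- function(i, j) oracle_H(bins[i, ], bins[j, ])
    marg <- vapply(1:n, H, 0)
    o_sel <- which.max(marg)
    while (length(o_sel) < min(3, n)) {
      rem <- setdiff(1:n, o_sel)
      red <- vapply(rem, function(cand)
        max(vapply(o_sel, function(s)
          H(s) + H(cand) - Hj(s, cand), 0)), 0)
      o_sel <- c(o_sel, rem[which.min(red)])
    }
    expect_equal(sel$site, o_sel, info = paste("seed", seed))
  }
})

test_that("sensor count selection follows the variogram criterion", {
  set.seed(41)
  mod <- variogram_model("gaussian", nugget = 0.1, psill = 2, range = 12)
  f <- simulate_gaussian_field(30, 30, mod, seed = 41)
  mask <- all_water_mask(30, 30)
  st <- sample_stations(f, mask, 25, noise_sd = 0.1, seed = 42)
  cand <- generate_candidates(mask, spacing = 4)
  set.seed(43)
  cand <- cand[sample(nrow(cand), 20), ]
  vals <- raster_sample(f, cand$x, cand$y) + rnorm(20, 0, 0.1)

  # vacuous tolerance accepts the very first sensor
  d0 <- determine_sensor_count(st, cand, vals, tolerance = Inf)
  expect_equal(d0$k, 1)
  expect_true(d0$converged)

  # unattainable tolerance exhausts k_max with a warning
  expect_warning(
    dmax <- determine_sensor_count(st, cand, vals, tolerance = 1e-12,
                                   k_max = 10),
    "tolerance")
  expect_equal(dmax$k, 10)
  expect_false(dmax$converged)
  expect_equal(length(dmax$trace), 10)

  expect_error(determine_sensor_count(st, cand, vals, tolerance = 0),
               "tolerance")
})

test_that("virtual values from the same field keep k below k_max", {
  mod <- variogram_model("gaussian", nugget = 0.05, psill = 1, range = 10)
  ks <- integer(0)
  for (seed in 1:10) {
    f <- simulate_gaussian_field(25, 25, mod, seed = seed)
    mask <- all_water_mask(25, 25)
    st <- sample_stations(f, mask, 30, noise_sd = 0.05, seed = seed + 100)
    cand <- generate_candidates(mask, spacing = 5)
    set.seed(seed)
    cand <- cand[sample(nrow(cand)), ]
    vals <- raster_sample(f, cand$x, cand$y) + rnorm(nrow(cand), 0, 0.05)
    d <- suppressWarnings(
      determine_sensor_count(st, cand, vals, tolerance = 0.25))
    ks <- c(ks, if (d$converged) d$k else NA_integer_)
  }
  expect_gte(sum(!is.na(ks) & ks < 25), 6)   # stabilizes well below k_max mostly
})
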