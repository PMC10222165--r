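test_that("vech stacks the lower triangle in lexicographic order", {
  expect_equal(vech(matrix(c(5, 2, 2, 7), 2)), c(5, 2, 7))
  expect_equal(vech(diag(2)), c(1, 0, 1))
  m3 <- matrix(c(1, 2, 3, 2, 5, 6, 3, 6, 9), 3)
  expect_equal(vech(m3), c(1, 2, 3, 5, 6, 9))
  expect_error(vech(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("design matrix rows are the offset monomials", {
  X0 <- taylor_design(c(0, 0), rbind(c(1, 1), c(2, 2)), order = 0)
  expect_equal(X0, matrix(1, 2, 1))
  X1 <- taylor_design(c(0, 0), rbind(c(2, 3), c(0, 0), c(1, 1)), order = 1)
  expect_equal(X1[1, ], c(1, 2, 3))
  X2 <- taylor_design(c(1, 1), rbind(c(2, 3), c(0, 0), c(1, 1),
                                     c(3, 1), c(0, 2), c(2, 0)), order = 2)
  expect_equal(X2[1, ], c(1, 1, 2, 1, 2, 4))     # offsets (1,2)
  expect_equal(X2[, 1], rep(1, 6))
  expect_error(taylor_design(c(0, 0), rbind(c(1, 1)), order = 1), "neighbor")
})

test_that("kernel weights follow the bandwidth-matrix formula", {
  expect_equal(kernel_weight(c(0, 0), diag(2)), 1 / (2 * pi))
  d <- c(1.2, -0.7)
  r2 <- sum(d^2)
  expect_equal(kernel_weight(d, diag(2)), exp(-r2 / 2) / (2 * pi))
  # W = 2I flattens the decay by exactly (1/4) exp(3 r^2 / 8)
  expect_equal(kernel_weight(d, 2 * diag(2)) / kernel_weight(d, diag(2)),
               exp(3 * r2 / 8) / 4)
  # symmetric in d <-> -d
  W <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(kernel_weight(d, W), kernel_weight(-d, W))
  # epanechnikov compact support
  expect_equal(kernel_weight(c(2, 0), diag(2), "epanechnikov"), 0)
  expect_error(kernel_weight(d, matrix(0, 2, 2)), "positive definite")
})

test_that("solve_local reproduces closed forms", {
  set.seed(10)
  nb <- cbind(runif(12, -3, 3), runif(12, -3, 3))
  k <- runif(12, 0.1, 1)
  g <- rnorm(12)
  # order 0: weighted mean
  f0 <- solve_local(g, taylor_design(c(0, 0), nb, 0), k)
  expect_equal(f0$beta[1], sum(k * g) / sum(k))
  # constants reproduced exactly, weights sum to 1
  fc <- solve_local(rep(3.7, 12), taylor_design(c(0, 0), nb, 2), k)
  expect_equal(fc$beta[1], 3.7)
  expect_equal(sum(fc$weights), 1, tolerance = 1e-12)
  # degree-2 polynomial reproduced regardless of weights
  poly <- function(p) 2 - p[, 1] + 0.5 * p[, 2] + 0.3 * p[, 1]^2 -
    0.2 * p[, 1] * p[, 2] + 0.1 * p[, 2]^2
  f2 <- solve_local(poly(nb), taylor_design(c(0, 0), nb, 2), k)
  expect_equal(f2$beta[1], poly(matrix(c(0, 0), 1)), tolerance = 1e-8)
  expect_error(solve_local(g, taylor_design(c(0, 0), nb, 2), rep(0, 12)),
               "positive")
})

test_that("the intercept is invariant to rescaling non-constant columns", {
  set.seed(12)
  nb <- cbind(runif(10, -2, 2), runif(10, -2, 2))
  X <- taylor_design(c(0, 0), nb, 2)
  k <- runif(10, 0.2, 1)
  g <- rnorm(10)
  b1 <- solve_local(g, X, k)$beta[1]
  S <- diag(c(1, 2, 0.5, 4, 10, 0.25))     # any invertible column scaling
  b2 <- solve_local(g, X %*% S, k)$beta[1]
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("equivalent weights sum to 1 over random configurations", {
  set.seed(77)
  worst <- 0
  for (i in 1:200) {
    order_ <- sample(0:2, 1)
    q <- (order_ + 1) * (order_ + 2) / 2
    M <- sample(max(q, 10):25, 1)
    nb <- cbind(runif(M, -50, 50), runif(M, -50, 50))
    X <- taylor_design(c(0, 0), nb, order_)
    # bandwidths comparable to the domain scale so gaussian weights stay
    # representable (solve_local's precondition of >= q positive weights)
    W <- if (runif(1) < 0.5) diag(2) * runif(1, 8, 60) else {
      A <- matrix(rnorm(4, sd = 3), 2); crossprod(A) + diag(10, 2)
    }
    k <- kernel_weight(nb, W)
    fit <- solve_local(rnorm(M), X, k)
    worst <- max(worst, abs(sum(fit$weights) - 1))
  }
  expect_lt(worst, 1e-10)
})

test_that("pilot gradients recover a plane and vanish on constants", {
  set.seed(15)
  co <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  gr <- pilot_gradients(co, 2 * co[, 1] + 3 * co[, 2] + 1, sigma = 3, M = 12)
  expect_equal(max(abs(gr[, 1] - 2)), 0, tolerance = 1e-8)
  expect_equal(max(abs(gr[, 2] - 3)), 0, tolerance = 1e-8)
  grc <- pilot_gradients(co, rep(5, 40), sigma = 3, M = 12)
  expect_lt(max(abs(grc)), 1e-8)
})

test_that("steering matrices align with the field's directional structure", {
  set.seed(16)
  co <- cbind(runif(80, 0, 20), runif(80, 0, 20))
  # field varying only along x: kernels should elongate along y
  gr <- pilot_gradients(co, sin(co[, 1] / 3), sigma = 2, M = 12)
  st <- steering_matrices(co, gr, lambda = 0.1, M = 12)
  for (i in sample(80, 10)) {
    C <- matrix(st$Chalf[i, c(1, 2, 2, 3)], 2)
    C <- C %*% C                       # back to C from its square root
    e <- eigen(C, symmetric = TRUE)
    ang <- abs(atan2(e$vectors[2, 2], e$vectors[1, 2]))  # smallest-eigval vec
    expect_lt(min(abs(ang - pi / 2), abs(ang + pi / 2 - pi)), 10 * pi / 180)
  }
  expect_gt(median(st$anisotropy), 1.5)

  # isotropic noise: near-isotropic steering
  grn <- matrix(rnorm(160), 80, 2)
  stn <- steering_matrices(co, grn, lambda = 1, M = 30)
  expect_lt(median(stn$anisotropy), 1.1)

  # lambda -> Inf recovers W = sigma I exactly (det-normalized)
  stinf <- steering_matrices(co, gr, lambda = 1e9, M = 12)
  expect_equal(stinf$Chalf[1, ], c(1, 0, 1), tolerance = 1e-6)

  # zero gradients with lambda = 0 is singular
  expect_error(steering_matrices(co, matrix(0, 80, 2), lambda = 0),
               "singular")
})

test_that("determinant of the steering shape is one (sigma stays a bandwidth)", {
  set.seed(17)
  co <- cbind(runif(30, 0, 10), runif(30, 0, 10))
  gr <- pilot_gradients(co, co[, 1]^2 - co[, 2], sigma = 3, M = 10)
  st <- steering_matrices(co, gr, lambda = 0.2, M = 10)
  dets <- st$Chalf[, 1] * st$Chalf[, 3] - st$Chalf[, 2]^2   # det of C^(1/2)
  expect_equal(dets, rep(1, 30), tolerance = 1e-10)
})
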