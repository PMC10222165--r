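#' Half-vectorization of a symmetric matrix
#'
#' Stacks the lower triangle column by column in lexicographic order:
#' `vech([[a,b],[b,d]]) = (a, b, d)`;
#' `vech` of a symmetric 3x3 gives `(a, b, c, e, f, i)` for rows
#' `(a b c; b e f; c f i)`.
#'
#' @param m symmetric numeric matrix (checked to 1e-12).
#' @return numeric vector of length `n(n+1)/2`.
#' @export
vech <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12)
    stop("vech requires a symmetric matrix")
  m[lower.tri(m, diag = TRUE)]
}

#' Local Taylor design matrix
#'
#' Row i holds the monomials of the offset `d_i = p_i - p` up to the given
#' order: `(1)`, `(1, dx, dy)`, or `(1, dx, dy, dx^2, dx*dy, dy^2)`. The
#' quadratic block is the `vech` of `d d^T` in plain monomial convention; the
#' intercept estimate is invariant to any invertible rescaling of the
#' non-constant columns, so coefficient-scaling conventions cannot affect the
#' concentration estimate (derivative read-outs are documented against this
#' basis: `beta1 = (du/dx, du/dy)`, and the quadratic coefficients are
#' `(uxx/2, uxy, uyy/2)`).
#'
#' @param center numeric length-2 estimation point `p`.
#' @param neighbors M x 2 matrix of sample coordinates.
#' @param order polynomial order N in 0:2.
#' @return M x q design matrix, `q = (N+1)(N+2)/2`.
#' @export
taylor_design <- function(center, neighbors, order = 2) {
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  neighbors <- matrix(as.numeric(neighbors), ncol = 2)
  q <- (order + 1) * (order + 2) / 2
  if (nrow(neighbors) < q)
    stop("need at least q = ", q, " neighbors for order ", order,
         "; enlarge the neighborhood")
  dx <- neighbors[, 1] - center[1]
  dy <- neighbors[, 2] - center[2]
  X <- cbind(1, dx, dy, dx^2, dx * dy, dy^2, deparse.level = 0)
  X[, seq_len(q), drop = FALSE]
}

#' Anisotropic kernel weight
#'
#' Evaluates `K_W(d) = det(W)^(-1) K(W^(-1) d)` for a 2x2 symmetric
#' positive-definite bandwidth matrix `W`. `K` is a radially symmetric 2-D
#' kernel: gaussian `K(t) = (2*pi)^(-1) exp(-||t||^2 / 2)` or Epanechnikov
#' `K(t) = (2/pi) (1 - ||t||^2)` on the unit disc. Larger `W` flattens the
#' decay; weights are symmetric in `d <-> -d`.
#'
#' @param d offset vector (or 2-column matrix of offsets), metres.
#' @param W 2x2 symmetric positive-definite bandwidth matrix.
#' @param kernel `"gaussian"` or `"epanechnikov"`.
#' @return numeric weight(s), strictly positive for the gaussian kernel.
#' @export
kernel_weight <- function(d, W, kernel = c("gaussian", "epanechnikov")) {
  kernel <- match.arg(kernel)
  W <- as.matrix(W)
  detW <- W[1, 1] * W[2, 2] - W[1, 2] * W[2, 1]
  if (max(abs(W - t(W))) > 1e-10 || detW <= 0 || W[1, 1] <= 0)
    stop("W must be symmetric positive definite")
  d <- matrix(as.numeric(d), ncol = 2)
  t_ <- d %*% t(solve(W))
  r2 <- rowSums(t_^2)
  k <- switch(kernel,
              gaussian = exp(-r2 / 2) / (2 * pi),
              epanechnikov = (2 / pi) * pmax(0, 1 - r2))
  k / detW
}

#' Solve the local weighted least-squares system
#'
#' Solves `min_b ||g - X b||^2_K` giving `b = (X'KX)^(-1) X'K g` and extracts
#' the equivalent kernel weights `w` such that `beta0 = sum(w * g)`. Because
#' the first design column is the constant 1, the weights always sum to 1 --
#' the estimator reproduces constants exactly. Kernel weights are rescaled by
#' their maximum before solving (the solution is invariant to a positive
#' rescaling of K). If the normal matrix is ill-conditioned (condition number
#' above 1e12) a small ridge `1e-8 tr(X'KX)/q` is added and flagged.
#'
#' @param g numeric responses at the M neighbors.
#' @param X M x q design from [taylor_design()].
#' @param k non-negative kernel weights, at least q strictly positive.
#' @return list with `beta`, `weights`, `cond`, `ridge` (logical).
#' @export
solve_local <- function(g, X, k) {
  X <- as.matrix(X)
  M <- nrow(X); q <- ncol(X)
  if (length(g) != M || length(k) != M) stop("dimension mismatch")
  if (any(k < 0)) stop("kernel weights must be non-negative")
  if (sum(k > 0) < q) stop("need at least q = ", q, " strictly positive weights")
  ks <- k / max(k)
  # solve in a column-scaled basis: beta0 and the equivalent weights are
  # invariant to rescaling the non-constant columns, and the scaling keeps
  # the normal matrix well conditioned for metre-scale offsets
  s <- apply(abs(X), 2, max)
  s[s == 0] <- 1
  X <- X %*% diag(1 / s, q)
  rk <- sqrt(ks)
  A <- X * rk
  dec <- qr(A)
  ridge <- FALSE
  if (dec$rank == q) {
    R <- qr.R(dec)
    cond <- kappa(R, exact = TRUE)^2       # condition of the normal matrix
    if (is.finite(cond) && cond <= 1e12) {
      # (X'KX)^-1 X'K = R^-1 Q' diag(sqrt(ks))
      B <- backsolve(R, t(qr.Q(dec))) * rep(rk, each = q)
      beta <- drop(B %*% g) / s
      return(list(beta = beta, weights = B[1, ] / s[1], cond = cond,
                  ridge = FALSE))
    }
  }
  # ill-conditioned or rank-deficient layout: ridge-regularized normal
  # equations (the weight-sum identity then holds only approximately)
  XtKX <- crossprod(X, X * ks)
  cond <- kappa(XtKX, exact = TRUE)
  XtKX <- XtKX + diag(1e-8 * sum(diag(XtKX)) / q + 1e-300, q)
  ch <- tryCatch(chol(XtKX), error = function(e)
    stop("rank-deficient local system even after ridge (", M,
         " neighbors, condition ", format(cond), ")"))
  B <- chol2inv(ch) %*% t(X * ks)
  beta <- drop(B %*% g) / s
  list(beta = beta, weights = B[1, ] / s[1], cond = cond, ridge = TRUE)
}

# ---- internal prediction engine ------------------------------------------

# Chalf: n x 3 matrix (c11, c12, c22) of per-sample C^(1/2) factors; the
# bandwidth matrix of sample i is W_i = sigma * C_i^(-1/2), so the kernel
# argument is t = C^(1/2) d / sigma. Isotropic fits use Chalf = identity.
# The normalizing 1/det(W) factor is constant across samples (det C = 1 by
# construction) and cancels from the weighted solve, so it is omitted here.
tsch_engine <- function(pts, coords, values, Chalf, sigma, kernel, order, M,
                        exclude = NULL, max_extrapolation = 2) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  n <- nrow(coords)
  q <- (order + 1) * (order + 2) / 2
  out <- matrix(NA_real_, nrow(pts), 6,
                dimnames = list(NULL, c("value", "gx", "gy", "cond", "ridge",
                                        "neighbors")))
  idx_all <- seq_len(n)
  for (j in seq_len(nrow(pts))) {
    keep <- if (is.null(exclude)) idx_all else idx_all[-exclude[j]]
    if (length(keep) < q) next
    dx <- coords[keep, 1] - pts[j, 1]
    dy <- coords[keep, 2] - pts[j, 2]
    d2 <- dx * dx + dy * dy
    m <- min(M, length(keep))
    ord <- order(d2, keep)[seq_len(m)]
    nb <- keep[ord]
    ddx <- dx[ord]; ddy <- dy[ord]
    # outside the sampled region a polynomial fit extrapolates wildly; the
    # local model degrades to the order-0 weighted mean when the point is
    # beyond max_extrapolation bandwidths from the nearest sample, or lies
    # outside the neighborhood's bounding box by more than half its radius
    # (one-sided extrapolation)
    ox <- max(0, min(ddx), -max(ddx))
    oy <- max(0, min(ddy), -max(ddy))
    q_here <- if (sqrt(d2[ord[1]]) > max_extrapolation * sigma ||
                  ox * ox + oy * oy > (0.5 * sigma)^2) 1L else q
    X <- cbind(1, ddx, ddy, ddx^2, ddx * ddy, ddy^2,
               deparse.level = 0)[, seq_len(q_here), drop = FALSE]
    c11 <- Chalf[nb, 1]; c12 <- Chalf[nb, 2]; c22 <- Chalf[nb, 3]
    sig <- sigma
    repeat {
      tx <- (c11 * ddx + c12 * ddy) / sig
      ty <- (c12 * ddx + c22 * ddy) / sig
      r2 <- tx * tx + ty * ty
      if (kernel == "gaussian") {
        k <- exp(-(r2 - min(r2)) / 2)      # rescaled; solve is scale-invariant
        break
      }
      k <- pmax(0, 1 - r2)
      if (sum(k > 0) >= q_here) break
      sig <- sig * 2                       # widen a too-narrow compact kernel
      if (sig > sigma * 2^40) break
    }
    if (sum(k > 0) < q_here) next
    fit <- tryCatch(solve_local(values[nb], X, k), error = function(e) NULL)
    if (is.null(fit)) next
    out[j, "value"] <- fit$beta[1]
    if (q_here >= 3) { out[j, "gx"] <- fit$beta[2]; out[j, "gy"] <- fit$beta[3] }
    out[j, "cond"] <- fit$cond
    out[j, "ridge"] <- as.numeric(fit$ridge)
    out[j, "neighbors"] <- m
  }
  out
}

#' Isotropic pilot fit: local gradients at sample locations
#'
#' Stage one of the two-stage steering scheme: an isotropic-kernel local
#' linear fit at every sample location, exposing the gradient estimates
#' `beta1 = (du/dx, du/dy)` that the steering matrices are built from. Each
#' sample's own value participates in its pilot fit.
#'
#' @param coords n x 2 sample coordinates (metres).
#' @param values numeric sample values.
#' @param sigma isotropic bandwidth (metres).
#' @param M neighborhood size.
#' @param kernel kernel family.
#' @return n x 2 matrix of gradients.
#' @export
pilot_gradients <- function(coords, values, sigma, M = 10,
                            kernel = "gaussian") {
  iso <- matrix(rep(c(1, 0, 1), each = nrow(coords)), ncol = 3)
  res <- tsch_engine(coords, coords, values, iso, sigma, kernel, order = 1,
                     M = max(M, 3))
  res[, c("gx", "gy"), drop = FALSE]
}

#' Build per-sample steering matrices from pilot gradients
#'
#' For each sample i, the gradients of the target field (and, optionally, of
#' importance-weighted standardized covariates) over its M-nearest
#' neighborhood are stacked into a Jacobian `J_i`; the local gradient
#' covariance is `F_i = J_i' J_i / m`. The steering shape is the regularized,
#' determinant-normalized covariance
#' `C_i = (F_i + lambda * tr(F_i + eps I)/2 * I) / sqrt(det(.))`,
#' and the bandwidth matrix is `W_i = sigma * C_i^(-1/2)`: the kernel
#' stretches along directions in which the field varies slowly, so smoothing
#' follows iso-concentration structure instead of blurring across it. The
#' determinant normalization keeps `sigma` an honest bandwidth in metres and
#' makes `lambda -> Inf` recover the isotropic `W = sigma I` exactly. With
#' `lambda = 0` and vanishing gradients the matrix is singular and an error
#' is raised; any positive `lambda` degrades gracefully to near-isotropic.
#'
#' @param coords n x 2 sample coordinates.
#' @param gradients n x 2 pilot gradients of the target (from
#'   [pilot_gradients()]).
#' @param covariate_gradients optional list of n x 2 gradient matrices, one
#'   per retained covariate (already standardized).
#' @param importances non-negative weight per covariate channel.
#' @param lambda regularization (>= 0); trades anisotropy against stability.
#' @param epsilon small floor inside the trace term.
#' @param M neighborhood size used for the local covariance.
#' @return list with `Chalf` (n x 3 rows `(c11, c12, c22)` of `C_i^(1/2)`)
#'   and `anisotropy` (per-sample ratio of kernel axis lengths, >= 1).
#' @export
steering_matrices <- function(coords, gradients, covariate_gradients = NULL,
                              importances = NULL, lambda = 0.1,
                              epsilon = 1e-8, M = 10) {
  n <- nrow(coords)
  if (lambda < 0) stop("lambda must be >= 0")
  channels <- list(gradients)
  wts <- 1
  if (!is.null(covariate_gradients) && length(covariate_gradients)) {
    if (is.null(importances)) importances <- rep(1, length(covariate_gradients))
    if (any(importances < 0)) stop("importances must be >= 0")
    channels <- c(channels, covariate_gradients)
    wts <- c(1, importances)
  }
  Chalf <- matrix(NA_real_, n, 3)
  aniso <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2
    nb <- order(d2, seq_len(n))[seq_len(min(M, n))]
    J <- do.call(rbind, lapply(seq_along(channels), function(c_)
      wts[c_] * channels[[c_]][nb, , drop = FALSE]))
    J <- J[stats::complete.cases(J), , drop = FALSE]
    Fi <- if (nrow(J)) crossprod(J) / nrow(J) else matrix(0, 2, 2)
    Ci <- Fi + diag(lambda * (sum(diag(Fi)) + 2 * epsilon) / 2, 2)
    detC <- Ci[1, 1] * Ci[2, 2] - Ci[1, 2]^2
    if (detC <= 0)
      stop("singular steering matrix at sample ", i,
           " (zero gradients with lambda = 0); use lambda > 0")
    Ci <- Ci / sqrt(detC)
    e <- eigen(Ci, symmetric = TRUE)
    half <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
    Chalf[i, ] <- c(half[1, 1], half[1, 2], half[2, 2])
    aniso[i] <- sqrt(max(e$values) / min(e$values))
  }
  list(Chalf = Chalf, anisotropy = aniso)
}

# ---- covariate screening --------------------------------------------------

#' Rank covariates and keep the dominant ones
#'
#' Permutation importance from a random forest of `value ~ covariates`;
#' covariates with importance above the mean importance are retained as the
#' dominant explanatory variables that steer the kernels.
#'
#' @param stations [station_set] with covariate columns.
#' @param covariates names to screen (default: all covariate columns).
#' @param seed RNG seed for the forest.
#' @param ntree forest size.
#' @return data.frame `covariate`, `importance`, `dominant`, ordered by
#'   decreasing importance.
#' @export
dominant_covariates <- function(stations, covariates = covariate_names(stations),
                                seed = 1L, ntree = 500) {
  ok <- !is.na(stations$value) &
    stats::complete.cases(stations[, covariates, drop = FALSE])
  if (sum(ok) < 5) stop("need >= 5 complete rows to rank covariates")
  set.seed(seed)
  fit <- randomForest::randomForest(
    stations[ok, covariates, drop = FALSE], stations$value[ok],
    ntree = ntree, importance = TRUE)
  imp <- randomForest::importance(fit, type = 1)[, 1]
  imp <- pmax(imp, 0)
  out <- data.frame(covariate = names(imp), importance = unname(imp),
                    dominant = unname(imp) > mean(imp))
  out[order(-out$importance), ]
}
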