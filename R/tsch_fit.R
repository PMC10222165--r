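#' Fit a TSCH spatial estimator
#'
#' TSCH (Taylor-expansion estimation under Spatial Correlation and spatial
#' Heterogeneity) models a concentration surface `u(p)` around every
#' estimation point by a local Taylor polynomial
#' `u(p_i) ~ beta0 + beta1'(p_i - p) + ...` fitted by kernel-weighted least
#' squares over the M nearest samples. The intercept `beta0` is the estimate
#' at `p` and is a convex-like combination `sum(w_i g_i)` of neighboring
#' observations with equivalent weights summing to 1. Spatial heterogeneity
#' enters through per-sample steering matrices: anisotropic bandwidths built
#' from pilot gradient covariances of the target and of its dominant
#' covariates, so the kernel stretches along directions of slow variation.
#'
#' The fit object stores the samples and all kernel machinery; prediction at
#' new points or over a water mask happens in [predict.tsch()]. When `sigma`
#' is not given it is chosen by leave-one-out cross-validation on a
#' log-spaced grid between the median nearest-neighbor spacing and the
#' domain half-diagonal.
#'
#' @param formula `value ~ covariates` (use `~ 1` for none, `~ .` for all
#'   covariate columns). The response names the concentration column; the
#'   right-hand side names covariates used only for kernel steering.
#' @param data a [station_set] or data.frame with planar coordinate columns.
#' @param coords names of the x and y columns (metres).
#' @param order Taylor order N in 0:2 (default 2, the full quadratic).
#' @param kernel `"gaussian"` (default) or `"epanechnikov"`.
#' @param sigma global bandwidth in metres; `NULL` = select by LOOCV.
#' @param sigma_grid candidate bandwidths for the LOOCV search.
#' @param neighbors local window size M; default `max(3q, 10)`.
#' @param steering use anisotropic steering kernels (two-stage fit).
#' @param lambda steering regularization (>= 0); larger is closer to
#'   isotropic.
#' @param epsilon floor inside the steering trace term.
#' @param max_extrapolation estimation points farther than this many
#'   bandwidths from their nearest sample fall back to the order-0 weighted
#'   mean instead of extrapolating the local polynomial.
#' @param importance optional named vector of covariate channel weights;
#'   `NULL` = rank by random-forest permutation importance and keep the
#'   dominant ones.
#' @param seed RNG seed for the covariate-ranking forest.
#' @return object of class `"tsch"`.
#' @seealso [predict.tsch()], [residuals.tsch()], [summary.tsch()],
#'   [estimate_field()]
#' @examples
#' set.seed(1)
#' d <- data.frame(id = 1:40, x = runif(40, 0, 100), y = runif(40, 0, 100))
#' d$value <- 5 + 0.03 * d$x + rnorm(40, 0, 0.1)
#' fit <- tsch(value ~ 1, d, sigma = 25, steering = FALSE)
#' predict(fit, data.frame(x = 50, y = 50))
#' @export
tsch <- function(formula = value ~ 1, data, coords = c("x", "y"), order = 2,
                 kernel = c("gaussian", "epanechnikov"), sigma = NULL,
                 sigma_grid = NULL, neighbors = NULL, steering = TRUE,
                 lambda = 0.1, epsilon = 1e-8, max_extrapolation = 2,
                 importance = NULL, seed = 1L) {
  kernel <- match.arg(kernel)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  cl <- match.call()
  data <- as.data.frame(data)
  if (!all(coords %in% names(data)))
    stop("coordinate columns not found: ", paste(coords, collapse = ", "))
  resp <- all.vars(formula[[2]])
  if (!resp %in% names(data)) stop("response column '", resp, "' not found")
  covars <- attr(stats::terms(formula,
                              data = data[, setdiff(names(data),
                                                    c(coords, "id", "source")),
                                          drop = FALSE]), "term.labels")
  covars <- intersect(covars, names(data))
  keep <- !is.na(data[[resp]])
  if (!all(keep)) data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  q <- (order + 1) * (order + 2) / 2
  if (n < q) stop("need at least q = ", q, " samples for order ", order)
  M <- if (is.null(neighbors)) max(3 * q, 10) else neighbors
  M <- min(M, n)
  if (M < q) stop("neighbors must be >= q = ", q)
  coords_m <- as.matrix(data[, coords])
  values <- data[[resp]]

  if (is.null(sigma_grid)) {
    if (n >= 2) {
      d <- as.matrix(stats::dist(coords_m))
      diag(d) <- Inf
      nn <- stats::median(apply(d, 1, min))
      span <- sqrt(diff(range(coords_m[, 1]))^2 + diff(range(coords_m[, 2]))^2)
      sigma_grid <- exp(seq(log(max(nn, span * 1e-3, 1e-6)),
                            log(max(span / 2, nn * 2, 1e-6)),
                            length.out = 8))
    } else sigma_grid <- 1
  }
  iso <- matrix(rep(c(1, 0, 1), each = n), ncol = 3)

  loo_rmse <- function(Chalf, sig) {
    pr <- tsch_engine(coords_m, coords_m, values, Chalf, sig, kernel, order, M,
                      exclude = seq_len(n), max_extrapolation = max_extrapolation)
    sqrt(mean((pr[, "value"] - values)^2, na.rm = TRUE))
  }
  sigma_iso <- sigma
  if (is.null(sigma_iso)) {
    rmse <- vapply(sigma_grid, function(s) loo_rmse(iso, s), 0)
    sigma_iso <- sigma_grid[which.min(rmse)]
  }

  Chalf <- iso
  grads <- NULL
  imp_table <- NULL
  aniso <- rep(1, n)
  sigma_final <- sigma_iso
  if (steering) {
    grads <- pilot_gradients(coords_m, values, sigma_iso, M = M, kernel = kernel)
    cov_grads <- NULL
    imp_w <- NULL
    if (length(covars)) {
      if (is.null(importance)) {
        imp_table <- tryCatch(
          dominant_covariates(station_set(cbind(
            data.frame(id = seq_len(n), x = coords_m[, 1], y = coords_m[, 2],
                       value = values),
            data[, covars, drop = FALSE])), covariates = covars, seed = seed),
          error = function(e) NULL)
        if (!is.null(imp_table)) {
          kept <- imp_table$covariate[imp_table$dominant]
          imp_w <- imp_table$importance[imp_table$dominant]
          if (length(kept)) imp_w <- imp_w / max(imp_w)
          covars_used <- kept
        } else covars_used <- character(0)
      } else {
        covars_used <- intersect(names(importance), covars)
        imp_w <- unname(importance[covars_used])
      }
      if (length(covars_used)) {
        cov_grads <- lapply(covars_used, function(cv) {
          z <- data[[cv]]
          z <- (z - mean(z, na.rm = TRUE)) / max(stats::sd(z, na.rm = TRUE), 1e-12)
          z[is.na(z)] <- 0
          pilot_gradients(coords_m, z, sigma_iso, M = M, kernel = kernel)
        })
        names(cov_grads) <- covars_used
      }
    }
    g2 <- grads; g2[is.na(g2)] <- 0
    st <- steering_matrices(coords_m, g2, cov_grads, imp_w, lambda = lambda,
                            epsilon = epsilon, M = M)
    Chalf <- st$Chalf
    aniso <- st$anisotropy
    if (is.null(sigma)) {
      rmse <- vapply(sigma_grid, function(s) loo_rmse(Chalf, s), 0)
      sigma_final <- sigma_grid[which.min(rmse)]
    } else sigma_final <- sigma
  }

  structure(list(
    call = cl, formula = formula, data = data, coords = coords,
    response = resp, covariates = covars, order = order, q = q, M = M,
    kernel = kernel, sigma = sigma_final, sigma_iso = sigma_iso,
    sigma_grid = sigma_grid, steering = steering, lambda = lambda,
    epsilon = epsilon, max_extrapolation = max_extrapolation, n = n, coords_matrix = coords_m, values = values,
    Chalf = Chalf, pilot_gradients = grads, anisotropy = aniso,
    importance = imp_table, seed = seed), class = "tsch")
}

#' Predict from a TSCH fit
#'
#' @param object a [tsch()] fit.
#' @param newdata either a data.frame with the fit's coordinate columns, or a
#'   logical [wq_raster] water mask (prediction at every water cell center).
#' @param what `"value"` returns the concentration estimates only; `"full"`
#'   additionally returns gradient estimates, the local condition number,
#'   whether the ridge fallback fired, and the neighbor count.
#' @param ... unused.
#' @return For point `newdata`: a numeric vector (`what = "value"`) or
#'   data.frame (`what = "full"`). For a mask: a `"tsch_field"` (see
#'   [estimate_field()]).
#' @export
predict.tsch <- function(object, newdata, what = c("value", "full"), ...) {
  what <- match.arg(what)
  if (inherits(newdata, "wq_raster"))
    return(estimate_field(object, newdata, gradients = what == "full"))
  pts <- as.matrix(as.data.frame(newdata)[, object$coords])
  res <- tsch_engine(pts, object$coords_matrix, object$values, object$Chalf,
                     object$sigma, object$kernel, object$order, object$M,
                     max_extrapolation = object$max_extrapolation)
  if (what == "value") unname(drop(res[, "value"])) else as.data.frame(res)
}

#' Estimate the concentration field over a water mask
#'
#' Runs the local fit at every water cell center and assembles the results
#' into rasters: the concentration estimate (`beta0`), optional gradient
#' components, and a condition-number diagnostics layer. Cells where the
#' local system cannot be solved are nodata.
#'
#' @param fit a [tsch()] fit.
#' @param mask logical [wq_raster]; estimates are produced on `TRUE` cells.
#' @param gradients also return `du/dx`, `du/dy` rasters (needs order >= 1).
#' @return object of class `"tsch_field"`: list of [wq_raster]s `estimate`,
#'   (`gx`, `gy`,) `cond`, plus `n_unsolved`.
#' @export
estimate_field <- function(fit, mask, gradients = FALSE) {
  stopifnot(inherits(fit, "tsch"), inherits(mask, "wq_raster"))
  wc <- water_cells(mask)
  if (nrow(wc) == 0L) stop("mask has no water cells")
  res <- tsch_engine(cbind(wc$x, wc$y), fit$coords_matrix, fit$values,
                     fit$Chalf, fit$sigma, fit$kernel, fit$order, fit$M,
                     max_extrapolation = fit$max_extrapolation)
  blank <- function() {
    m <- matrix(NA_real_, nrow(mask$values), ncol(mask$values))
    m
  }
  put <- function(col, units = "") {
    m <- blank()
    m[cbind(wc$row, wc$col)] <- res[, col]
    wq_raster(m, origin = mask$origin, cell_size = mask$cell_size,
              nodata = mask$nodata, units = units)
  }
  out <- list(estimate = put("value", "mg/L"), cond = put("cond"),
              n_unsolved = sum(is.na(res[, "value"])))
  if (gradients && fit$order >= 1) {
    out$gx <- put("gx", "mg/L/m"); out$gy <- put("gy", "mg/L/m")
  }
  structure(out, class = "tsch_field")
}

#' @export
print.tsch_field <- function(x, ...) {
  cat("<tsch_field>\n")
  print(x$estimate)
  if (x$n_unsolved > 0) cat("  unsolved cells:", x$n_unsolved, "\n")
  invisible(x)
}

#' @export
plot.tsch_field <- function(x, which = "estimate", ...) {
  r <- x[[which]]
  nr <- nrow(r$values); nc <- ncol(r$values)
  xs <- r$origin[1] + (seq_len(nc) - 0.5) * r$cell_size
  ys <- r$origin[2] - (rev(seq_len(nr)) - 0.5) * r$cell_size
  graphics::image(xs, ys, t(r$values[nr:1, , drop = FALSE]),
                  xlab = "x (m)", ylab = "y (m)", main = which,
                  col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE, ...)
  invisible(x)
}

# leave-one-out predictions at the fit's own stations
tsch_loo <- function(object) {
  res <- tsch_engine(object$coords_matrix, object$coords_matrix, object$values,
                     object$Chalf, object$sigma, object$kernel, object$order,
                     object$M, exclude = seq_len(object$n),
                     max_extrapolation = object$max_extrapolation)
  drop(res[, "value"])
}

#' @export
fitted.tsch <- function(object, ...) {
  drop(tsch_engine(object$coords_matrix, object$coords_matrix, object$values,
                   object$Chalf, object$sigma, object$kernel, object$order,
                   object$M,
                   max_extrapolation = object$max_extrapolation)[, "value"])
}

#' Residuals of a TSCH fit
#'
#' `type = "loo"` (default) gives leave-one-out residuals -- each station is
#' removed and predicted from the rest, the honest assessment for a local
#' smoother, which interpolates its own stations almost exactly.
#' `type = "response"` gives in-sample residuals.
#'
#' @param object a [tsch()] fit.
#' @param type `"loo"` or `"response"`.
#' @param ... unused.
#' @export
residuals.tsch <- function(object, type = c("loo", "response"), ...) {
  type <- match.arg(type)
  pred <- if (type == "loo") tsch_loo(object) else fitted(object)
  object$values - pred
}

#' @export
print.tsch <- function(x, ...) {
  cat("TSCH spatial estimator\n")
  src <- if (is.null(x$data$source)) rep("monitoring", x$n) else x$data$source
  cat(sprintf("  %d samples (%d monitoring, %d virtual), order N = %d, M = %d neighbors\n",
              x$n, sum(src != "virtual"), sum(src == "virtual"), x$order, x$M))
  cat(sprintf("  kernel: %s, sigma = %.4g m, %s\n", x$kernel, x$sigma,
              if (x$steering)
                sprintf("steering (lambda = %.3g, median anisotropy %.2f)",
                        x$lambda, stats::median(x$anisotropy))
              else "isotropic"))
  if (!is.null(x$importance) && any(x$importance$dominant))
    cat("  dominant covariates:",
        paste(x$importance$covariate[x$importance$dominant], collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.tsch <- function(object, ...) {
  loo <- tsch_loo(object)
  ok <- !is.na(loo)
  met <- compute_metrics(object$values[ok], loo[ok])
  structure(list(fit = object, loo_metrics = met,
                 value_range = range(object$values)), class = "summary.tsch")
}

#' @export
print.summary.tsch <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  sample values: %.3g to %.3g mg/L\n",
              x$value_range[1], x$value_range[2]))
  cat(sprintf("  LOOCV: R^2 = %s, MAE = %.4g, RMSE = %.4g (m = %d)\n",
              ifelse(is.na(x$loo_metrics$r2), "NA",
                     sprintf("%.3f", x$loo_metrics$r2)),
              x$loo_metrics$mae, x$loo_metrics$rmse, x$loo_metrics$m))
  invisible(x)
}

#' @export
plot.tsch <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(64, "viridis")
  v <- x$values
  ci <- pmin(pmax(findInterval(v, seq(min(v), max(v), length.out = 65),
                               rightmost.closed = TRUE), 1L), 64L)
  src <- if (is.null(x$data$source)) rep("monitoring", x$n) else x$data$source
  graphics::plot(x$coords_matrix, col = cols[ci],
                 pch = ifelse(src == "virtual", 17, 19),
                 xlab = "x (m)", ylab = "y (m)", main = "samples", asp = 1, ...)
  loo <- tsch_loo(x)
  graphics::plot(x$values, loo, xlab = "observed (mg/L)",
                 ylab = "LOO predicted (mg/L)", main = "leave-one-out")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
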