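#' Empirical semivariogram (Matheron estimator)
#'
#' For every pair of stations whose separation falls in a lag bin,
#' gamma(h) = 1 / (2 N(h)) * sum (z_i - z_j)^2. Bins are equal-width on
#' `(0, max_lag]`; pairs beyond `max_lag` are ignored. Empty bins are kept in
#' the output with `count = 0` and `gamma = NA` so that two estimates computed
#' on the same bin edges stay comparable bin by bin.
#'
#' @param stations a [station_set] (rows with `NA` values are dropped).
#' @param n_bins number of equal-width lag bins.
#' @param max_lag largest separation considered, metres. Default: half the
#'   diagonal of the station bounding box, the customary reliable extent of
#'   an empirical variogram.
#' @return data.frame of class `"variogram_estimate"` with columns
#'   `bin_center` (m), `gamma` ((value units)^2) and `count`; attributes
#'   `edges` and `variance` (sample variance of the values, used by
#'   [variogram_distance()]).
#' @export
empirical_variogram <- function(stations, n_bins = 12, max_lag = NULL) {
  s <- stations[!is.na(stations$value), , drop = FALSE]
  if (nrow(s) < 2) stop("need at least 2 stations with values")
  d <- as.matrix(stats::dist(cbind(s$x, s$y)))
  if (is.null(max_lag)) {
    span <- sqrt(diff(range(s$x))^2 + diff(range(s$y))^2)
    max_lag <- span / 2
  }
  if (!is.finite(max_lag) || max_lag <= 0) stop("max_lag must be positive")
  ut <- upper.tri(d)
  h <- d[ut]
  dz2 <- (outer(s$value, s$value, "-")^2)[ut]
  keep <- h > 0 & h <= max_lag
  h <- h[keep]; dz2 <- dz2[keep]
  edges <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(h, edges, left.open = TRUE), 1L), n_bins)
  count <- tabulate(bin, nbins = n_bins)
  gamma <- rep(NA_real_, n_bins)
  pop <- which(count > 0)
  for (b in pop) gamma[b] <- sum(dz2[bin == b]) / (2 * count[b])
  if (length(pop) == 1L && n_bins > 1L)
    warning("all pairwise distances fall in a single lag bin")
  out <- data.frame(bin_center = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    gamma = gamma, count = count)
  attr(out, "edges") <- edges
  attr(out, "variance") <- stats::var(s$value)
  class(out) <- c("variogram_estimate", "data.frame")
  out
}

#' Evaluate a fitted variogram model at lags h
#'
#' @param model a `"variogram_model"` from [fit_variogram_model()] or
#'   [variogram_model()].
#' @param h numeric lag distances (m).
#' @return semivariance at each lag; `model(0) = nugget` by convention
#'   (the theoretical discontinuity at the origin).
#' @export
variogram_eval <- function(model, h) {
  n <- model$nugget; s <- model$psill; r <- model$range
  structural <- switch(model$family,
    spherical   = ifelse(h >= r, s, s * (1.5 * h / r - 0.5 * (h / r)^3)),
    exponential = s * (1 - exp(-h / r)),
    gaussian    = s * (1 - exp(-(h / r)^2)),
    stop("unknown variogram family: ", model$family))
  n + structural
}

#' Construct a variogram model from known parameters
#'
#' @param family one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget zero-lag variance (>= 0).
#' @param psill partial sill (>= 0); total sill = nugget + psill.
#' @param range correlation length parameter (> 0), metres.
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget = 0, psill = 1, range = 1) {
  family <- match.arg(family)
  if (nugget < 0 || psill < 0 || range <= 0)
    stop("need nugget >= 0, psill >= 0, range > 0")
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range), class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, partial sill %.4g, range %.4g m\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Fit a variogram model to an empirical estimate
#'
#' Weighted least squares over (nugget, partial sill, range), with pair
#' counts as weights, optimized by bounded quasi-Newton (L-BFGS-B) from the
#' standard robust start (nugget 0, sill = sample variance, range = median
#' populated lag). If the optimizer reports non-convergence, an error is
#' raised carrying the best iterate in its condition (`best` field).
#'
#' @param est a `"variogram_estimate"`.
#' @param family model family to fit.
#' @return a `"variogram_model"` with an `sse` attribute (weighted SSE).
#' @export
fit_variogram_model <- function(est, family = c("spherical", "exponential",
                                                "gaussian")) {
  family <- match.arg(family)
  pop <- !is.na(est$gamma) & est$count > 0
  if (sum(pop) < 3) stop("need at least 3 populated lag bins to fit a model")
  h <- est$bin_center[pop]; g <- est$gamma[pop]; w <- est$count[pop]
  v <- attr(est, "variance")
  if (is.null(v) || !is.finite(v) || v <= 0) v <- max(g)
  obj <- function(p) {
    m <- list(family = family, nugget = p[1], psill = p[2], range = p[3])
    sum(w * (variogram_eval(m, h) - g)^2)
  }
  start <- c(nugget = 0, psill = v, range = stats::median(h))
  lower <- c(0, 0, max(1e-8, min(h) * 1e-3))
  upper <- c(max(g) * 2 + v, max(g) * 2 + v, max(h) * 10)
  fit <- stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 500))
  # restart from a long-range initial point if the first fit stalled high
  alt <- stats::optim(c(0, v, max(h)), obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 500))
  if (alt$value < fit$value) fit <- alt
  if (!fit$convergence %in% c(0, 51)) {
    cond <- structure(
      class = c("tsch_variogram_error", "error", "condition"),
      list(message = paste0("variogram fit did not converge (code ",
                            fit$convergence, ")"),
           call = sys.call(), best = fit$par))
    stop(cond)
  }
  out <- variogram_model(family, nugget = fit$par[1], psill = fit$par[2],
                         range = fit$par[3])
  attr(out, "sse") <- fit$value
  out
}

#' Normalized distance between two empirical variograms
#'
#' Root-mean-square difference of gamma over the lag bins populated in both
#' estimates, normalized by the sample variance of the first set's values, so
#' the distance is dimensionless and comparable across months. Returns `Inf`
#' when the two estimates share no populated bin. Both estimates must have
#' been computed on identical bin edges.
#'
#' @param a,b `"variogram_estimate"` objects on the same bins; `a` is the
#'   reference whose variance normalizes the distance.
#' @return non-negative scalar (or `Inf`).
#' @export
variogram_distance <- function(a, b) {
  ea <- attr(a, "edges"); eb <- attr(b, "edges")
  if (is.null(ea) || is.null(eb) || length(ea) != length(eb) ||
      !isTRUE(all.equal(ea, eb)))
    stop("variogram estimates were not computed on identical bin edges")
  common <- !is.na(a$gamma) & !is.na(b$gamma)
  if (!any(common)) return(Inf)
  v <- attr(a, "variance")
  if (is.null(v) || !is.finite(v) || v <= 0)
    stop("reference estimate has no positive sample variance")
  sqrt(mean((a$gamma[common] - b$gamma[common])^2)) / v
}

#' Write a variogram estimate to CSV
#' @param est a `"variogram_estimate"`.
#' @param path output path.
#' @export
write_variogram <- function(est, path) {
  utils::write.csv(as.data.frame(est), path, row.names = FALSE)
  invisible(path)
}
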