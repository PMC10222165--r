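#' Accuracy metrics for paired observations and estimates
#'
#' `R^2 = 1 - sum((y_obs - y_est)^2) / sum((y_obs - mean(y_obs))^2)`,
#' `MAE = mean(|y_est - y_obs|)`, `RMSE = sqrt(mean((y_est - y_obs)^2))`.
#' If the observations have zero variance, R^2 is undefined and returned as
#' `NA` while MAE/RMSE are still computed. The descriptive standard
#' deviations of both vectors are attached for reporting.
#'
#' @param observed measured values `y*` (mg/L).
#' @param estimated estimated values `y` (mg/L), same length.
#' @return list of class `"tsch_metrics"`: `r2`, `mae`, `rmse`, `m`,
#'   `sd_observed`, `sd_estimated`.
#' @export
compute_metrics <- function(observed, estimated) {
  m <- length(observed)
  if (m < 1L || length(estimated) != m)
    stop("observed and estimated must have equal positive length")
  if (anyNA(observed) || anyNA(estimated))
    stop("metrics require complete pairs; drop failed folds first")
  ss_res <- sum((observed - estimated)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  structure(list(
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    mae = mean(abs(estimated - observed)),
    rmse = sqrt(mean((estimated - observed)^2)),
    m = m,
    sd_observed = stats::sd(observed),
    sd_estimated = stats::sd(estimated)), class = "tsch_metrics")
}

#' @export
print.tsch_metrics <- function(x, ...) {
  cat(sprintf("R^2 = %s, MAE = %.4g, RMSE = %.4g (m = %d)\n",
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)), x$mae,
              x$rmse, x$m))
  invisible(x)
}

#' Leave-one-out cross-validation of a spatial predictor
#'
#' Each monitoring station is removed in turn and predicted from the
#' remaining stations; virtual sensors (rows with `source == "virtual"`)
#' always stay on the training side and are never held out, since only
#' laboratory-measured stations can validate the method. The predictor is an
#' arbitrary function, so retrieval models and estimator settings can be
#' refit inside every fold, avoiding leakage of the held-out station.
#'
#' @param stations [station_set]; rows with missing values are skipped.
#' @param predictor `function(train, newdata)` returning one predicted value
#'   per row of `newdata`; `train` is a station_set (monitoring + virtual),
#'   `newdata` a data.frame with the held-out station's row.
#' @param virtual optional [station_set] of virtual sensors appended to
#'   every training fold. Alternatively a `function(train)` returning such a
#'   set, to regenerate virtual values per fold.
#' @return list of class `"cv_report"`: `folds` (id, observed, predicted,
#'   failed), `metrics` ([compute_metrics] over successful folds),
#'   `n_failed`.
#' @export
loocv <- function(stations, predictor, virtual = NULL) {
  mon <- stations[(is.null(stations$source) |
                     stations$source != "virtual") & !is.na(stations$value), ,
                  drop = FALSE]
  m <- nrow(mon)
  if (m < 3) stop("need >= 3 monitoring stations for leave-one-out validation")
  pred <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    train <- mon[-i, , drop = FALSE]
    virt <- if (is.function(virtual)) virtual(train) else virtual
    if (!is.null(virt)) {
      virt <- virt[!is.na(virt$value), , drop = FALSE]
      common <- intersect(names(train), names(virt))
      train <- rbind(train[, common, drop = FALSE], virt[, common, drop = FALSE])
    }
    pred[i] <- tryCatch(
      as.numeric(predictor(train, mon[i, , drop = FALSE]))[1],
      error = function(e) NA_real_)
  }
  failed <- is.na(pred)
  if (any(failed))
    warning(sum(failed), " fold(s) failed and were excluded from the metrics")
  structure(list(
    folds = data.frame(id = mon$id, observed = mon$value, predicted = pred,
                       failed = failed),
    metrics = compute_metrics(mon$value[!failed], pred[!failed]),
    n_failed = sum(failed)), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds (%d failed): ", nrow(x$folds), x$n_failed))
  print(x$metrics)
  invisible(x)
}

#' Inverse-distance-weighted interpolation
#'
#' Baseline interpolator: `u(p) = sum(w_i g_i) / sum(w_i)` with
#' `w_i = d_i^(-power)`. A target within 1e-9 m of a station returns that
#' station's value exactly.
#'
#' @param stations [station_set] with values.
#' @param targets data.frame with `x`, `y`.
#' @param power distance exponent (default 2).
#' @param n_neighbors number of nearest stations used (default: all).
#' @return numeric vector of interpolated values.
#' @export
idw_interpolate <- function(stations, targets, power = 2,
                            n_neighbors = Inf) {
  s <- stations[!is.na(stations$value), , drop = FALSE]
  if (nrow(s) < 1) stop("need at least one station with a value")
  vapply(seq_len(nrow(targets)), function(j) {
    d <- sqrt((s$x - targets$x[j])^2 + (s$y - targets$y[j])^2)
    hit <- which(d < 1e-9)
    if (length(hit)) return(s$value[hit[1]])
    if (is.finite(n_neighbors) && n_neighbors < length(d)) {
      nb <- order(d, seq_along(d))[seq_len(n_neighbors)]
      d <- d[nb]; v <- s$value[nb]
    } else v <- s$value
    w <- d^(-power)
    sum(w * v) / sum(w)
  }, 0)
}

#' Ordinary kriging
#'
#' Best linear unbiased prediction under a fitted variogram model: solves
#' the standard ordinary-kriging system with the unbiasedness constraint, so
#' the weights at every target sum to 1, and the predictor is exact at
#' station locations when the nugget is zero.
#'
#' @param stations [station_set] with values (no duplicate locations).
#' @param model a [variogram_model()].
#' @param targets data.frame with `x`, `y`.
#' @param return_weights also return the weight matrix.
#' @return numeric vector of predictions (or a list with `predictions` and
#'   `weights`).
#' @export
ordinary_kriging <- function(stations, model, targets,
                             return_weights = FALSE) {
  s <- stations[!is.na(stations$value), , drop = FALSE]
  n <- nrow(s)
  if (n < 3) stop("need >= 3 stations for ordinary kriging")
  d <- as.matrix(stats::dist(cbind(s$x, s$y)))
  dup <- which(d < 1e-9 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup))
    stop("duplicate station locations: ",
         paste(apply(dup, 1, function(ij)
           paste(s$id[ij[1]], s$id[ij[2]], sep = "/")), collapse = ", "))
  G <- variogram_eval(model, d)
  diag(G) <- 0                       # gamma(0) = 0 for the kriging system
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  preds <- numeric(nrow(targets))
  Wmat <- if (return_weights) matrix(NA_real_, nrow(targets), n) else NULL
  for (j in seq_len(nrow(targets))) {
    d0 <- sqrt((s$x - targets$x[j])^2 + (s$y - targets$y[j])^2)
    g0 <- variogram_eval(model, d0)
    g0[d0 < 1e-12] <- 0
    sol <- solve(A, c(g0, 1))
    w <- sol[seq_len(n)]
    preds[j] <- sum(w * s$value)
    if (return_weights) Wmat[j, ] <- w
  }
  if (return_weights) list(predictions = preds, weights = Wmat) else preds
}

#' Compare interpolation methods by leave-one-out cross-validation
#'
#' Convenience wrapper running [loocv()] for any of the built-in methods --
#' TSCH (steering or isotropic), IDW and ordinary kriging -- on the same
#' folds, with identical training data.
#'
#' @param stations monitoring [station_set].
#' @param methods subset of `c("tsch", "tsch_iso", "idw", "kriging")`.
#' @param virtual optional virtual-sensor [station_set] (or generator
#'   function), training-side only.
#' @param tsch_args list of arguments passed to [tsch()] (e.g. `sigma`,
#'   `order`, `lambda`).
#' @param idw_power IDW exponent.
#' @param variogram_family kriging variogram family.
#' @return named list of `"cv_report"` objects.
#' @export
evaluate_methods <- function(stations,
                             methods = c("tsch", "tsch_iso", "idw", "kriging"),
                             virtual = NULL, tsch_args = list(),
                             idw_power = 2,
                             variogram_family = "spherical") {
  methods <- match.arg(methods, several.ok = TRUE)
  predictors <- list(
    tsch = function(train, newdata) {
      fit <- do.call(tsch, c(list(formula = value ~ 1, data = train,
                                  steering = TRUE), tsch_args))
      predict(fit, newdata)
    },
    tsch_iso = function(train, newdata) {
      fit <- do.call(tsch, c(list(formula = value ~ 1, data = train,
                                  steering = FALSE), tsch_args))
      predict(fit, newdata)
    },
    idw = function(train, newdata)
      idw_interpolate(train, newdata, power = idw_power),
    kriging = function(train, newdata) {
      est <- empirical_variogram(train)
      mod <- fit_variogram_model(est, variogram_family)
      ordinary_kriging(train, mod, newdata)
    })
  out <- lapply(methods, function(m) loocv(stations, predictors[[m]], virtual))
  stats::setNames(out, methods)
}
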