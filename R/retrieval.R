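#' Default candidate band list
#'
#' The eight 10 m / 20 m Sentinel-2 reflectance bands customarily screened
#' for optically active water-quality retrieval: blue (B2), green (B3), red
#' (B4), three red-edge bands (B5-B7), NIR (B8) and SWIR1 (B11). Eight bands
#' give 2^8 - 1 = 255 non-empty subsets for the exhaustive search.
#' @export
default_bands <- function() {
  c("blue", "green", "red", "red1", "red2", "red3", "nir", "swir1")
}

#' Enumerate all non-empty band subsets
#'
#' Deterministic order: by subset size, then lexicographically within a size
#' (band names sorted alphabetically first). The count is exactly
#' `2^length(band_names) - 1`.
#'
#' @param band_names character vector (1 to 12 names, no duplicates).
#' @param max_size optional cap on subset size, to keep the O(2^B) search
#'   tractable for large B.
#' @return list of character vectors.
#' @export
enumerate_band_subsets <- function(band_names, max_size = length(band_names)) {
  if (length(band_names) == 0L) stop("band list must be non-empty")
  if (length(band_names) > 12L) stop("more than 12 candidate bands; use max_size")
  if (anyDuplicated(band_names)) stop("duplicate band names")
  sorted <- sort(band_names)
  out <- list()
  for (s in seq_len(min(max_size, length(sorted)))) {
    combs <- utils::combn(sorted, s, simplify = FALSE)
    out <- c(out, combs)
  }
  out
}

#' Extract per-point band reflectances
#'
#' Samples the containing cell of each point for every band of the subset.
#' Rows touching nodata in any band are flagged (`complete = FALSE`) so that
#' callers can exclude them from training.
#'
#' @param scene an [ms_scene].
#' @param points data.frame with `x`, `y` (and ideally `id`).
#' @param subset character vector of band names.
#' @return data.frame with one column per band plus a logical `complete`
#'   column.
#' @export
extract_features <- function(scene, points, subset) {
  stopifnot(inherits(scene, "ms_scene"))
  missing <- setdiff(subset, names(scene))
  if (length(missing)) stop("scene is missing band(s): ",
                            paste(missing, collapse = ", "))
  ref <- scene[[1]]
  rc <- point_cell(ref, points$x, points$y)
  if (anyNA(rc$row)) {
    ids <- if (!is.null(points$id)) points$id[is.na(rc$row)] else which(is.na(rc$row))
    stop("points outside raster extent: ", paste(ids, collapse = ", "))
  }
  feats <- as.data.frame(lapply(scene[subset], function(b)
    b$values[cbind(rc$row, rc$col)]))
  names(feats) <- subset
  feats$complete <- stats::complete.cases(feats)
  feats
}

# leave-one-out cross-validated R^2 of a random forest on (X, y)
rf_loocv_r2 <- function(X, y, ntree, seed) {
  n <- length(y)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(seed + i)
    fit <- randomForest::randomForest(X[-i, , drop = FALSE], y[-i],
                                      ntree = ntree)
    pred[i] <- stats::predict(fit, X[i, , drop = FALSE])
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) -Inf else 1 - sum((y - pred)^2) / ss_tot
}

#' Exhaustive band-subset search for concentration retrieval
#'
#' Fits a random-forest regressor of station concentration on each band
#' subset's reflectances and scores it by leave-one-out cross-validated R^2
#' (the only stable protocol at typical station counts of ~14). Returns the
#' best subset and a forest refit on all stations with it. Subsets are
#' visited in [enumerate_band_subsets()] order and ties favour the earlier
#' (smaller, then lexicographically first) subset. A best score below
#' `reliability` (default 0.75, the customary acceptance bar for retrieval
#' models) is flagged `reliable = FALSE`.
#'
#' @param scene an [ms_scene].
#' @param stations monitoring [station_set] with >= 5 non-missing values.
#' @param band_names candidate bands (default [default_bands()] intersected
#'   with the scene).
#' @param seed integer; makes the search bit-reproducible.
#' @param ntree forest size.
#' @param max_size cap on subset size.
#' @param reliability acceptance bar on the best LOO R^2.
#' @return list of class `"retrieval_model"`: `subset`, `model` (the refit
#'   forest), `score`, `scores` (full table), `reliable`, `seed`,
#'   `train_range`.
#' @export
select_best_combination <- function(scene, stations,
                                    band_names = intersect(default_bands(),
                                                           names(scene)),
                                    seed = 1L, ntree = 500,
                                    max_size = length(band_names),
                                    reliability = 0.75) {
  ok <- !is.na(stations$value)
  if (sum(ok) < 5) stop("need >= 5 stations with values")
  stations <- stations[ok, , drop = FALSE]
  subsets <- enumerate_band_subsets(band_names, max_size = max_size)
  all_feats <- extract_features(scene, stations, band_names)
  keep <- all_feats$complete
  if (sum(keep) < 5) stop("fewer than 5 stations with complete band data")
  y <- stations$value[keep]
  scores <- vapply(seq_along(subsets), function(j) {
    X <- all_feats[keep, subsets[[j]], drop = FALSE]
    rf_loocv_r2(X, y, ntree = ntree, seed = seed)
  }, 0)
  scores[is.nan(scores)] <- -Inf
  best <- if (all(!is.finite(scores))) 1L else which.max(scores)
  # earlier subset wins ties: smaller, then lexicographic
  subset <- subsets[[best]]
  set.seed(seed)
  model <- randomForest::randomForest(all_feats[keep, subset, drop = FALSE], y,
                                      ntree = ntree)
  structure(list(
    subset = subset, model = model, score = scores[best],
    scores = data.frame(subset = vapply(subsets, paste, "", collapse = "+"),
                        size = lengths(subsets), r2 = scores),
    reliable = scores[best] >= reliability,
    seed = seed, ntree = ntree,
    train_range = range(y)), class = "retrieval_model")
}

#' @export
print.retrieval_model <- function(x, ...) {
  cat(sprintf("<retrieval_model> best subset: %s (LOO R^2 = %.3f%s)\n",
              paste(x$subset, collapse = " + "), x$score,
              if (x$reliable) "" else "; below the 0.75 reliability bar"))
  invisible(x)
}

#' Predict concentrations for virtual sensors
#'
#' Applies a fitted retrieval model to the scene reflectances at the sensor
#' locations. Forest predictions are averages of training responses, so they
#' never leave the training target range. Sensors falling on nodata cells
#' get `NA` values.
#'
#' @param object a `"retrieval_model"`.
#' @param scene the [ms_scene] to sample.
#' @param sensors data.frame with `x`, `y` (and optionally `id`).
#' @return [station_set] of the sensors with predicted `value` and
#'   `source = "virtual"`.
#' @export
predict_virtual_values <- function(object, scene, sensors) {
  stopifnot(inherits(object, "retrieval_model"))
  feats <- extract_features(scene, sensors, object$subset)
  value <- rep(NA_real_, nrow(feats))
  if (any(feats$complete))
    value[feats$complete] <- stats::predict(
      object$model, feats[feats$complete, object$subset, drop = FALSE])
  ids <- if (!is.null(sensors$id)) sensors$id else sprintf("V%d", seq_len(nrow(feats)))
  station_set(data.frame(id = ids, x = sensors$x, y = sensors$y,
                         value = value, source = "virtual",
                         stringsAsFactors = FALSE))
}
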