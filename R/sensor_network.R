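#' Generate candidate virtual-sensor sites on the water surface
#'
#' Lays a regular grid of points at the given spacing over the mask extent
#' (points sit at the centers of `spacing`-sized blocks, so a spacing equal to
#' the cell size reproduces the cell centers) and keeps those falling on
#' water cells. Deterministic given mask and spacing. Manually chosen sites
#' (river confluences, poorly monitored arms) can be merged in via `extra`.
#'
#' @param mask logical [wq_raster] water mask.
#' @param spacing grid interval in metres (>= cell size).
#' @param extra optional data.frame with columns `x`, `y` of manual candidate
#'   locations; those off-water are dropped with a warning.
#' @return data.frame `id`, `x`, `y` of candidate sites.
#' @export
generate_candidates <- function(mask, spacing, extra = NULL) {
  stopifnot(inherits(mask, "wq_raster"))
  if (spacing < mask$cell_size) stop("spacing must be >= cell size")
  nr <- nrow(mask$values); nc <- ncol(mask$values)
  width <- nc * mask$cell_size; height <- nr * mask$cell_size
  xs <- mask$origin[1] + seq(spacing / 2, width, by = spacing)
  ys <- mask$origin[2] - seq(spacing / 2, height, by = spacing)
  pts <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  on_water <- raster_sample(mask, pts$x, pts$y) == 1
  pts <- pts[!is.na(on_water) & on_water, , drop = FALSE]
  if (!is.null(extra)) {
    ok <- raster_sample(mask, extra$x, extra$y) == 1
    if (any(is.na(ok) | !ok))
      warning(sum(is.na(ok) | !ok), " manual candidate(s) off water, dropped")
    extra <- extra[!is.na(ok) & ok, c("x", "y"), drop = FALSE]
    pts <- unique(rbind(pts[, c("x", "y")], extra))
  }
  if (nrow(pts) == 0L) stop("no candidate site falls on water")
  data.frame(id = sprintf("S%d", seq_len(nrow(pts))), x = pts$x, y = pts$y,
             row.names = NULL)
}

#' Discretize site realizations for entropy estimation
#'
#' Each candidate site carries T >= 2 realizations (e.g. monthly retrieved
#' concentrations); probabilities are estimated by an equal-width histogram
#' with shared bin edges spanning the pooled min-max range of all sites, so
#' that entropies are comparable across sites.
#'
#' @param realizations numeric matrix, one row per site, one column per
#'   realization.
#' @param n_bins number of histogram bins.
#' @return object of class `"entropy_model"` holding the per-site bin indices
#'   and the bin edges.
#' @export
entropy_model <- function(realizations, n_bins = 10) {
  realizations <- as.matrix(realizations)
  if (ncol(realizations) < 2) stop("need at least T = 2 realizations per site")
  if (any(!is.finite(realizations))) stop("realizations must be finite")
  rng <- range(realizations)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bins <- matrix(pmin(pmax(findInterval(realizations, edges,
                                        rightmost.closed = TRUE), 1L), n_bins),
                 nrow = nrow(realizations))
  structure(list(bins = bins, edges = edges, n_bins = as.integer(n_bins),
                 n_sites = nrow(realizations), t = ncol(realizations)),
            class = "entropy_model")
}

#' @export
print.entropy_model <- function(x, ...) {
  cat(sprintf("<entropy_model> %d sites x %d realizations, %d bins\n",
              x$n_sites, x$t, x$n_bins))
  invisible(x)
}

# -sum p log p with 0 log 0 := 0, from a count vector
entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Shannon entropy of one site
#'
#' E(S) = -sum_i p_i ln p_i over the site's histogram; measures how variable
#' (informative) the site's concentration record is. Bounded by `ln(n_bins)`.
#'
#' @param model an [entropy_model()].
#' @param site site index (row of the realization matrix).
#' @return entropy in nats.
#' @export
marginal_entropy <- function(model, site) {
  entropy_from_counts(tabulate(model$bins[site, ], nbins = model$n_bins))
}

#' Joint entropy of two (or more) sites
#'
#' E(S_a, S_b) = -sum_ij p_ij ln p_ij from the joint histogram of paired
#' realizations. With more than two sites the joint cell of each realization
#' is the tuple of bin indices; note that with short records the multi-way
#' histogram saturates quickly (at most T distinct cells).
#'
#' @param model an [entropy_model()].
#' @param sites integer vector of site indices.
#' @return joint entropy in nats.
#' @export
joint_entropy <- function(model, sites) {
  if (length(sites) == 1L) return(marginal_entropy(model, sites))
  if (length(sites) == 2L) {
    key <- model$bins[sites[1], ] + model$n_bins * (model$bins[sites[2], ] - 1L)
    return(entropy_from_counts(tabulate(key, nbins = model$n_bins^2)))
  }
  keys <- apply(model$bins[sites, , drop = FALSE], 2, paste, collapse = ",")
  entropy_from_counts(table(keys))
}

#' Conditional entropy E(target | given)
#'
#' Computed by the chain rule `E(A | B) = E(A, B) - E(B)`: the uncertainty
#' left in the target after observing the given site(s). Non-negative and at
#' most the marginal entropy of the target (up to histogram granularity).
#'
#' @param model an [entropy_model()].
#' @param target site index (or indices, treated jointly).
#' @param given site index or indices conditioned on.
#' @export
conditional_entropy <- function(model, target, given) {
  joint_entropy(model, c(target, given)) - joint_entropy(model, given)
}

#' Mutual information I(a; b) = E(a) + E(b) - E(a, b)
#' @inheritParams joint_entropy
#' @param a,b site indices (each may be a set, treated jointly).
#' @export
mutual_information <- function(model, a, b) {
  joint_entropy(model, a) + joint_entropy(model, b) - joint_entropy(model, c(a, b))
}

#' Greedy entropy-based ordering of candidate sites
#'
#' The first site maximizes marginal entropy (the most uncertain, hence most
#' informative, location). Each subsequent site minimizes its mutual
#' information with the already-selected set -- the redundancy
#' `I = E(selected) - E(selected | candidate)` -- so the network spreads over
#' independent parts of the water body. With short realization records the
#' multi-way joint entropy is poorly estimable, so by default the redundancy
#' is approximated by the pairwise surrogate `max over s in selected of
#' I(s; candidate)`; `exact = TRUE` uses the full multi-way histogram
#' (sensible only for long synthetic records). Ties are broken by the lowest
#' candidate index.
#'
#' @param model an [entropy_model()].
#' @param k_max number of sites to order (<= number of candidates).
#' @param exact use exact multi-way joint entropies instead of the pairwise
#'   surrogate.
#' @return data.frame `site` (index), `score` (entropy for the first pick,
#'   redundancy for the rest).
#' @export
greedy_select <- function(model, k_max, exact = FALSE) {
  n <- model$n_sites
  if (k_max > n) stop("k_max exceeds the number of candidates")
  if (k_max < 1) stop("k_max must be >= 1")
  marg <- vapply(seq_len(n), function(i) marginal_entropy(model, i), 0)
  sel <- which.max(marg)           # ties: which.max takes the lowest index
  scores <- marg[sel]
  # pairwise surrogate: carry the running max of I(s; cand) over selected s,
  # so each step only evaluates MI against the newest selection
  red_max <- rep(-Inf, n)
  while (length(sel) < k_max) {
    newest <- sel[length(sel)]
    remaining <- setdiff(seq_len(n), sel)
    if (exact) {
      red <- vapply(remaining, function(cand)
        mutual_information(model, sel, cand), 0)
    } else {
      for (cand in remaining)
        red_max[cand] <- max(red_max[cand],
                             mutual_information(model, newest, cand))
      red <- red_max[remaining]
    }
    pick <- remaining[which.min(red)]
    sel <- c(sel, pick)
    scores <- c(scores, min(red))
  }
  data.frame(site = sel, score = scores)
}

#' Choose the number of virtual sensors by semivariogram matching
#'
#' Virtual sensors are added one at a time in the greedy entropy order; after
#' each addition the semivariogram of the combined network (monitoring
#' stations + selected virtual sensors) is compared with the semivariogram of
#' the monitoring stations alone, on identical lag bins. The chosen network
#' size is the smallest k whose normalized variogram distance (see
#' [variogram_distance()]) drops below `tolerance`; if no k achieves it, all
#' `k_max` sensors are kept with a warning. The spatial-structure criterion
#' ensures the densified network still "looks like" the measured field.
#'
#' @param stations monitoring [station_set] with >= 3 values.
#' @param candidates data.frame `id`, `x`, `y` in greedy order (e.g. rows of
#'   [generate_candidates()] indexed by [greedy_select()]).
#' @param values retrieved concentration per candidate, same order.
#' @param tolerance acceptance threshold on the normalized variogram
#'   distance (> 0).
#' @param k_max largest network size tried (default: all candidates).
#' @param n_bins,max_lag variogram binning, shared by both estimates;
#'   `max_lag` defaults to half the diagonal of the combined bounding box.
#' @return list of class `"network_design"`: `k`, `sensors` (chosen rows with
#'   values), `trace` (distance per k), `converged`.
#' @export
determine_sensor_count <- function(stations, candidates, values, tolerance,
                                   k_max = nrow(candidates), n_bins = 12,
                                   max_lag = NULL) {
  if (!is.numeric(tolerance) || tolerance <= 0) stop("tolerance must be > 0")
  if (sum(!is.na(stations$value)) < 3) stop("need >= 3 monitoring values")
  if (length(values) != nrow(candidates))
    stop("one retrieved value per candidate required")
  k_max <- min(k_max, nrow(candidates))
  if (is.null(max_lag)) {
    ax <- range(c(stations$x, candidates$x)); ay <- range(c(stations$y, candidates$y))
    max_lag <- sqrt(diff(ax)^2 + diff(ay)^2) / 2
  }
  base <- empirical_variogram(stations, n_bins = n_bins, max_lag = max_lag)
  trace <- rep(NA_real_, k_max)
  chosen <- NA_integer_
  for (k in seq_len(k_max)) {
    virt <- data.frame(id = paste0("V", seq_len(k)),
                       x = candidates$x[seq_len(k)],
                       y = candidates$y[seq_len(k)],
                       value = values[seq_len(k)],
                       source = "virtual")
    comb <- station_set(rbind(
      as.data.frame(stations)[, c("id", "x", "y", "value", "source")],
      virt))
    est <- empirical_variogram(comb, n_bins = n_bins, max_lag = max_lag)
    trace[k] <- variogram_distance(base, est)
    if (is.na(chosen) && trace[k] < tolerance) { chosen <- k; break }
  }
  converged <- !is.na(chosen)
  if (!converged) {
    chosen <- k_max
    warning("variogram distance never dropped below tolerance; keeping k_max = ",
            k_max, " sensors")
  }
  sensors <- candidates[seq_len(chosen), , drop = FALSE]
  sensors$value <- values[seq_len(chosen)]
  sensors$source <- "virtual"
  structure(list(k = chosen, sensors = sensors,
                 trace = trace[seq_len(if (converged) chosen else k_max)],
                 tolerance = tolerance, converged = converged),
            class = "network_design")
}

#' @export
print.network_design <- function(x, ...) {
  cat(sprintf("<network_design> k = %d virtual sensors (%s; tolerance %.3g)\n",
              x$k, if (x$converged) "variogram criterion met" else "k_max reached",
              x$tolerance))
  cat("  distance trace:", paste(sprintf("%.3g", x$trace), collapse = " "), "\n")
  invisible(x)
}
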