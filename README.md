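# tsch — spatial water-quality fields from sparse stations and imagery

`tsch` estimates continuous water-quality concentration fields (e.g.
chemical oxygen demand, mg/L) over lakes and reservoirs from a sparse set of
monitoring stations, optionally densified with *virtual sensors* whose
values are retrieved from multispectral imagery. It is aimed at
environmental scientists and water-resource managers who have a handful of
laboratory-measured points, co-registered reflectance rasters, and need a
defensible concentration map with honest cross-validated accuracy.

## What it computes

**The TSCH estimator** (Taylor expansion under Spatial Correlation and
spatial Heterogeneity). At every estimation point *p* the field is modelled
locally as

    u(p_i) ≈ β₀ + β₁ᵀ(p_i − p) + ½ β₂ᵀ vech{(p_i − p)(p_i − p)ᵀ},

fitted by kernel-weighted least squares b̄ = (XᵀKX)⁻¹XᵀKg over the M nearest
samples; the estimate is the intercept β₀ = Σᵢ wᵢ gᵢ, whose equivalent
kernel weights always sum to 1. Kernel weights K_W(d) = det(W)⁻¹K(W⁻¹d) use
per-sample 2×2 bandwidth matrices W_i = σ C_i^(−1/2) *steered* by the local
gradient covariance of a pilot fit and of the dominant covariates
(turbidity, pH, temperature, ...), so smoothing stretches along
iso-concentration structure instead of blurring across it.

Around the estimator the package provides the full workflow:

* **NDWI water masking** — `(green − NIR)/(green + NIR)` with thresholding,
  defining the estimation domain;
* **virtual-sensor network design** — greedy Shannon-entropy/mutual-
  information site selection over a candidate grid, with the network size
  set by matching the densified network's semivariogram to that of the
  monitoring stations;
* **retrieval** — exhaustive band-subset search (2⁸ − 1 = 255 subsets for
  the canonical 8-band list) scored by leave-one-out R² of a random-forest
  regressor, then per-pixel prediction at the virtual sites;
* **validation** — leave-one-out cross-validation (virtual sensors stay on
  the training side) with R²/MAE/RMSE, against IDW and ordinary-kriging
  baselines;
* **synthetic data** — exact Gaussian-random-field worlds (anisotropic
  covariance, linked spectral bands, covariates, noisy stations) so the
  whole pipeline is testable without any external data.

## Worked example

A fully synthetic lake: 600 m × 600 m at 10 m cells, anisotropic
concentration field around 9 mg/L, 50 noisy stations, 6 spectral bands of
which 2 carry signal.

```r
library(tsch)

world <- make_synthetic_world(nrow = 60, ncol = 60, cell_size = 10,
                              n_stations = 50, seed = 42)

## retrieval: which band combination predicts the stations best?
ret <- select_best_combination(world$scene, world$stations,
                               names(world$scene), seed = 42, ntree = 300)
#> <retrieval_model> best subset: blue + green + red1 (LOO R^2 = 0.820)

## entropy-ordered candidate sites; network size by variogram matching
cand <- generate_candidates(world$mask, spacing = 60)
rlz  <- candidate_realizations(cand, 60, 60, world$params$model,
                               anisotropy = 3, mean_value = 9,
                               cell_size = 10, t = 12, seed = 43)
sel  <- greedy_select(entropy_model(rlz), k_max = 20)
virt <- predict_virtual_values(ret, world$scene, cand[sel$site, ])
des  <- determine_sensor_count(world$stations, cand[sel$site, ],
                               virt$value, tolerance = 0.25)
#> <network_design> k = 1 virtual sensors (variogram criterion met; tolerance 0.25)

## fit the steering-kernel estimator on stations + virtual sensors
merged <- station_set(rbind(
  as.data.frame(world$stations)[, c("id", "x", "y", "value", "source")],
  des$sensors[, c("id", "x", "y", "value", "source")]))
fit <- tsch(value ~ 1, merged, order = 2)
summary(fit)
#> TSCH spatial estimator
#>   51 samples (50 monitoring, 1 virtual), order N = 2, M = 18 neighbors
#>   kernel: gaussian, sigma = 41.72 m, steering (lambda = 0.1, median anisotropy 1.98)
#>   sample values: 6.66 to 11.1 mg/L
#>   LOOCV: R^2 = 0.639, MAE = 0.5858, RMSE = 0.7672 (m = 51)

field <- estimate_field(fit, world$mask)   # concentration raster on water
```

The bandwidth σ = 41.7 m was selected by leave-one-out search; the median
kernel anisotropy of 1.98 says the steering matrices stretched weights about
2:1 along the field's slow direction. Comparing methods on identical folds:

```r
cv <- evaluate_methods(world$stations,
                       methods = c("tsch", "tsch_iso", "idw", "kriging"),
                       virtual = des$sensors,
                       tsch_args = list(order = 2, sigma = fit$sigma))
#> tsch      R^2 = 0.6542, MAE = 0.5782, RMSE = 0.7571 (m = 50)
#> tsch_iso  R^2 = 0.6259, MAE = 0.6143, RMSE = 0.7875 (m = 50)
#> idw       R^2 = 0.3936, MAE = 0.8108, RMSE = 1.003  (m = 50)
#> kriging   R^2 = 0.6013, MAE = 0.6404, RMSE = 0.8131 (m = 50)
```

Steering reduces MAE by ~6% versus the isotropic kernel and ~29% versus IDW
here; each held-out station was predicted from the remaining 49 plus the
virtual sensor.

A thin command-line wrapper over these functions is installed at
`inst/cli/tsch-cli.R` (subcommands `simulate`, `mask`, `design-network`,
`retrieve`, `estimate`, `evaluate`).

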