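# dispkern

Estimating effective dispersal and density-dependent recruit survival from
settlement-collector experiments.

Passively dispersing sessile species — canopy-forming macroalgae are the
motivating case — release propagules that settle within metres of the
source. A standard field design places collector tiles of known area at
known distances and directions from the edge of an isolated source stand
and counts the recruits on each tile. `dispkern` turns those counts into
dispersal estimates:

* **Kernels.** The seven classical two-dimensional dispersal location
  kernels f(r) (negative exponential, Gaussian, power exponential, 2Dt,
  inverse Gaussian, log-normal, Weibull; scale *a*, shape *b*), each
  normalized over the plane, with the radial distance density
  k(r) = 2πr·f(r), CDFs, quantiles and means — closed forms plus an
  independent numeric-quadrature route.
* **Fitting.** Counts c on a tile of area A at distance r are Poisson with
  mean c = A·Q·f(r), Q the fitted propagule number. Maximum likelihood per
  site × direction × family, multi-start and reproducible; near-empty
  transects are excluded, not fitted.
* **Model selection.** AIC_i = −2 log L_i + 2V_i, ΔAIC, Akaike weights
  w_i = exp(−Δ_i/2)/Σ exp(−Δ_k/2), and the consensus best family across
  subsets (most frequent rank-1; ties broken by summed weight).
* **Dispersal distances.** Median and 95th-percentile distances from the
  selected kernel's distance distribution (Weibull: a(ln 2)^(1/b) and
  a(ln 20)^(1/b)), per subset and as grand means.
* **Survival.** Binomial logit GLM of yearly recruit survival inside vs
  outside the adult canopy (tiles at 0 m and 1 m only), with per-term Wald
  chi-square tests — the density-dependence test.
* **Synthetic experiments.** A generator reproducing the field layout (31
  collectors per site: 7 distances × 4 cardinal directions + 3 source
  collectors), Poisson settlement and binomial survival, for testing and
  power exploration.

## Worked example

```r
library(dispkern)

sim <- simulate_experiment(experiment_design(), synthetic_truth(seed = 7))
res <- run_fit(sim$counts)
res$consensus$family
#> [1] "gaussian"
res$distances$means
#>       q50       q95
#>  6.978196 14.507144
```

The default truth is a Weibull kernel with shape b = 2 — which is exactly
the Gaussian kernel — so AIC picks the more parsimonious Gaussian, and the
grand mean median (6.98 m) and 95th percentile (14.51 m) recover the
truth's 6.66 m and 13.85 m to within sampling error.

```r
sv <- run_survival(sim$survival)
sv$glm$wald
#>            term statistic df            p
#> 1      position 19.261831  1 0.0000113962
#> 2          site  3.952710  2 0.1385734308
#> 3 position:site  2.765074  2 0.2509410462
```

The positive `positionoutside` coefficient behind that Wald test means
survival is significantly *lower inside* the canopy — the negative
density-dependence the generator builds in (yearly survival 0.30 inside vs
0.55 outside).

A bundled table of published Weibull fits from a three-site experiment on
the fucoid *Cystoseira zosteroides* (`weibull_fit_table()`) makes a
real-data example: per site and orientation, `distance_quantile()` on the
(a, b) pair reproduces the reported median and 95th-percentile distances.

A thin command-line wrapper over the same functions is installed at
`inst/cli/dispkern.R` (subcommands `simulate`, `fit`, `survival`).

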