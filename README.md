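# leupmosaic

Entropy-based analysis of cone photoreceptor mosaics.

The avian retina packs five cone types — green, red, blue, violet and a
double cone — into interleaved spatial mosaics. Why do the types occur in
the particular proportions they do? `leupmosaic` implements an analysis
built on the Least microEnvironmental Uncertainty Principle (LEUP), which
posits that a differentiating cell picks its fate with probability

$$P(x_i) \;=\; \frac{e^{-\beta S(y|x_i)\, -\, \mu N(y|x_i)}}{Z(\beta,\mu)}
\qquad\xrightarrow[\ \mu=0,\ \text{Gaussian}\ y\ ]{}\qquad
Q_i(\beta) \;=\; \frac{\sigma_i^{-\beta}}{\sum_j \sigma_j^{-\beta}},$$

where $\sigma_i$ is the standard deviation of the nearest-neighbour
distance (NND) of type $i$'s mosaic and $\beta$ measures how strongly the
fate decision responds to microenvironmental uncertainty. $\beta = 2$
corresponds to minimum-variance (Berg–Purcell-optimal) sensing. The
package is aimed at quantitative biologists studying mosaic organisation
and cell-fate statistics.

It provides, as pipeable functions over data frames:

* **`fit_beta()`** — fit $\beta$ to observed cone proportions by
  Kullback–Leibler minimisation, with `tidy()` / `glance()` /
  `autoplot()` methods and a threshold-based plausibility interval.
* **`thermo_budget()` and friends** — a Crooks-type robustness bound for
  the progenitor-to-differentiated transition: metabolic heat, entropy
  change against the uniform pluripotent prior, and the maximal
  forward/backward probability ratio.
* **`entropy_production_f()` / `critical_radius()` /
  `feasible_region_scan()`** — the total-entropy-production landscape
  over the cell sensing radius $R$, its closed-form critical radius, and
  ternary feasibility rasters over the $(\beta_s, \beta_d,
  \tilde{\Delta\mu})$ space.
* **`solve_sensing_radius()` / `hyperuniformity_exponent()`** — invert
  the NND-variance model $\sigma^2(R) = M_1R^2 + M_2R\ln R + M_3R$ for
  per-type sensing radii and convert $(\sigma, \bar R)$ pairs into
  hyperuniformity exponents $A = 2\ln\sigma/\ln\bar R$.
* **`generate_mosaic()` / `nnd_statistics()` /
  `count_variance_exponent()` / `recovery_experiment()`** — seeded
  synthetic mosaics (jittered triangular lattices, Poisson, hard-core)
  and the estimators needed to validate the whole pipeline offline.
* **`run_pipeline()`** — all stages in order, from a fixture name, CSV or
  YAML config, to a deterministic JSON report.

The published chicken-retina summary statistics ship as the fixture
`kram2010_chicken` (proportions and NND standard deviations) and
`kram2010_chicken_radii` (per-type average sensing radii).

## Worked example

```r
library(leupmosaic)

fit <- fit_beta(cone_mosaic_fixture("kram2010_chicken"))
fit
#> LEUP beta fit: beta_hat = 1.7562, DKL_min = 0.004134 nats (search [0, 10])
tidy(fit)
#> # A tibble: 5 × 4
#>   label  observed fitted nnd_sd
#>   <chr>     <dbl>  <dbl>  <dbl>
#> 1 green     0.204 0.237   1.25
#> 2 red       0.16  0.163   1.55
#> 3 blue      0.133 0.134   1.73
#> 4 violet    0.094 0.0816  2.29
#> 5 double    0.409 0.385   0.948
```

The fitted sensitivity is close to 2: the observed cone proportions are
what optimal (minimum-variance) sensing of the local mosaic disorder
would produce, with less-variable mosaics hosting more frequent types.

The full pipeline adds the thermodynamic bookkeeping:

```r
run_pipeline()
#> LEUP mosaic analysis report
#>   beta_hat = 1.7562  (DKL_min = 0.004134 nats)
#>   S(differentiated) = 1.4737 nats, delta S = -0.1357 nats
#>   heat = 2929.4 kJ/mol, robustness margin = 9.3140 (robust)
#>   scenario min_landscape  r_c = 1.5811 (minimum)
#>   scenario max_landscape  r_c = 0.9129 (maximum)
#>   scenario avian_double   r_c = 0.9661 (minimum)
```

Reading the report: differentiation sharpens the fate distribution
(entropy change −0.136 nats against the uniform five-fate prior), but the
metabolic heat term (2929.4 kJ/mol at 310 K, i.e. 9.450 in the package's
dimensionless convention) dominates, leaving a robustness margin of 9.314
— the developed retina is overwhelmingly unlikely to dedifferentiate. The
landscape scenarios give the critical sensing radii at which total
entropy production is extremal, and their character (minimum vs maximum)
follows the sign of $\Gamma = (A\beta_d - D\beta_s)/2$.

## Documentation

The methods vignette (`vignettes/leup-mosaic-methods.Rmd`) describes the
model and its assumptions, the numerical choices, what the synthetic
generator does and does not emulate, and known limitations.
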