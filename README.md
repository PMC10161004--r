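# forestcti

Tools for detecting and decomposing **thermophilization** — the shift of
tree-community composition toward warm-adapted species — in repeat-census
forest inventory data, for forest ecologists and biogeographers working
with permanent-plot networks (plots of four circular 7.32 m subplots, a
12.7 cm DBH census threshold, a 2.5–12.7 cm sapling class).

## What it computes

**Species temperature indices.** Each species' thermal association (°C) is
estimated from occurrence records along a mean-annual-temperature gradient
by three methods: the simple niche mean, and the mean and optimum of a
penalized logistic response curve of presence vs background (`mgcv`).

**Community temperature index (CTI).** The basal-area-weighted mean of the
species indices over the stems present in a subplot at one census:

    CTI = Σ_t BA_t · I_s(t) / Σ_t BA_t,   BA = π (DBH/2)²

**Demographic decomposition.** The change in CTI between censuses is
decomposed by rebuilding the second census under counterfactual scenarios —
mortality only (survivors held at first-census size, recruits omitted),
growth only (deaths undone), recruitment only (deaths and growth undone) —
isolating each process's contribution Δ_mortality, Δ_growth,
Δ_recruitment.

**Derived predictors.** 15-year sliding-window climate changes (windows
t−19…t−5 and t−4…t+10 around the first-census year t), annual climatic
water deficit Σ_m max(0, PET_m − AET_m), McCune–Keon-style topographic heat
load with southwest aspect folding, standardization, and dummy or weighted
effect coding of fire/insect damage flags.

**Hierarchical Bayesian regression.** CTI at the two censuses is modeled
as

    Y_ijk ~ N(μ_ijk, σ²)
    μ_ijk = β0 + β1·x1k + Σ_m βm·x_mij + Σ_m β(m+10)·x1k·x_mij + u_i + v_ij

with a binary time indicator x1k, ten standardized predictors and their
time interactions, iid subplot effects v_ij ~ N(0, d²) and a plot-level
Matérn spatial Gaussian field u_i. Under weighted effect coding β1 is the
population-mean thermophilization per census interval. Coefficient priors
are flat; hyperparameters are estimated by restricted-marginal-likelihood
maximization with Laplace-mixture integration of their uncertainty (MCMC
optional).

A synthetic inventory generator with controllable mechanisms (niche-biased
mortality and growth, warming, damage flags, spatially autocorrelated
microclimate) makes the whole chain testable without external data. See the
methods vignette (`vignettes/thermophilization-methods.Rmd`) for the full
model description and design choices.

## Worked example

```r
library(forestcti)

cfg <- simulation_config(n_plots = 100, seed = 42)
res <- run_all(cfg, niche_method = "modeled_mean", n_occurrences = 300,
               variants = c("all", "mortality", "growth", "recruitment"))
print(res$fits[["all"]])
#> Hierarchical CTI regression (empirical_bayes), variant 'all', 800 rows
#>   beta0    9.1854  [  8.9401,   9.4307]
#>   beta1    0.2249  [  0.1639,   0.2859]
#>   sigma 0.4389  d 0.9552  sigma_u 0.2477  rho 11.01 km

res$effects[res$effects$term == "beta1", c("variant", "mean", "lower", "upper")]
#>      variant        mean        lower      upper
#>          all 0.224894833  0.163890222 0.28589944
#>    mortality 0.205157239  0.151024023 0.25929045
#>       growth 0.027341678  0.021610153 0.03307320
#>  recruitment 0.009208547 -0.003856379 0.02227347
```

Reading this: `beta0` is the mean baseline CTI of the simulated landscape
(≈9.2 °C); `beta1` says the average subplot's CTI rose by 0.225 °C over the
10-year census interval (0.0225 °C/y), with a 95% credible interval well
above zero. The variant rows decompose that signal: here the generator's
cool-niche mortality bias is the dominant mechanism (0.205 °C), with small
growth and negligible recruitment contributions — the decomposition
recovers the mechanism that was planted. `sigma`, `d`, `sigma_u` and `rho`
are the residual SD, subplot-effect SD, and the spatial field's SD and
range.

`run_all(cfg, outdir = "out")` additionally writes every stage artifact
(`trees.csv`, `species_indices.csv`, `cti.csv`, `decomposition.csv`,
`covariates.csv`, `effects.csv`, `effects.json`, `manifest.json`). A thin
command-line wrapper is installed at `inst/cli/forestcti.R`:

```sh
Rscript inst/cli/forestcti.R run-all --plots 100 --seed 42 --outdir out
```

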