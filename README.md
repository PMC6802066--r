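# occutrend

Bayesian multi-season occupancy modeling for regional trend assessment
from detection/nondetection surveys — the analysis framework used by
grid-based acoustic bat monitoring programs, where populations cannot be
counted directly and decline must be inferred from changes in the
probability that sample units are occupied.

## Who this is for

Monitoring programs that revisit a spatially balanced sample of grid cells
over several seasons, record a species as detected/not-detected on each
visit, and need to answer: *is the occupied range contracting?* — while
accounting for imperfect detection, and carrying information forward from
earlier monitoring periods through empirically informed priors.

## The model

Latent occupancy states follow an autologistic (autoregressive) Markov
process over seasons. For site *i* with standardized covariates
*x<sub>i</sub>* (forest cover, elevation, precipitation, topographic
roughness):

- Initial season: *z*(*i*,1) ~ Bernoulli(Ψ<sub>1i</sub>), with
  logit(Ψ<sub>1i</sub>) = β₀ + βᵀx<sub>i</sub>
- Transitions: *z*(*i*,*t*) | *z*(*i*,*t*−1) ~ Bernoulli(π<sub>ti</sub>),
  with logit(π<sub>ti</sub>) = a<sub>t</sub> + b<sub>t</sub> *z*(*i*,*t*−1)
  + βᵀx<sub>i</sub>
- Detection: *y*<sub>j</sub>(*i*,*t*) | *z*(*i*,*t*) ~
  Bernoulli(p<sub>it</sub> · *z*(*i*,*t*)), with logit(p) = α₀ + α₁·date
  (no false positives — detection histories are assumed verified)

Derived quantities, at average environmental conditions: persistence
φ<sub>t</sub> = logit⁻¹(a<sub>t</sub> + b<sub>t</sub>), colonization
γ<sub>t</sub> = logit⁻¹(a<sub>t</sub>), the recursive trajectory
Ψ<sub>t</sub> = Ψ<sub>t−1</sub>φ<sub>t</sub> + (1 −
Ψ<sub>t−1</sub>)γ<sub>t</sub>, and the occurrence growth rate λ =
Ψ<sub>T</sub>/Ψ<sub>1</sub> (with its annualization λ<sup>1/(T−1)</sup>),
the trend metric: λ < 1 indicates net range contraction.

Inference is by a blocked Gibbs sampler (Pólya-Gamma augmentation of both
logistic layers, single-site latent-state updates) written in C++, fully
reproducible from one seed. Priors are independent Normals: vague
(Normal(0,10) in the precision-0.1 reading, i.e. sd √10) or empirically
informed from a previous period's posterior summary — the package ships
the 2010 posterior summaries for two focal species (hoary bat, little
brown bat) and implements the posterior→prior scaffolding step for future
periods.

Diagnostics and evaluation: split-chain Gelman–Rubin R̂ with the
|R̂−1| < 0.1 rule, posterior AUC (per-draw Ψ scored against the same
draw's latent states), Moran's I spatial autocorrelation profiles of
occupancy residuals at 10–50 km, and vague-vs-informative
prior-sensitivity comparison. A synthetic survey generator (spatially
balanced site selection on a gridded frame with realistic covariate
fields, known ground truth) makes the whole pipeline testable without
field data.

## Worked example

```r
library(occutrend)

# a synthetic survey emulating the monitored design: 190 grid cells,
# 3 annual seasons (2016-2018), 4 single-night visits, declining truth
scenario <- scenario_config(seed = 2024, preset = "declining")
ds <- generate_dataset(scenario)
ds$truth$lambda_annual
#> [1] 0.86

# fit under empirically informed priors from the previous monitoring period
nm <- model_param_names(colnames(ds$data$covariates), n_transitions = 2)
priors <- informative_priors(period1_posterior_summary("hoary"), nm)
fit <- fit_model(ds$data, priors,
                 mcmc_config(seed = 1, n_chains = 3, n_burnin = 2000,
                             n_retained = 6000, thin = 2))

subset(summarize_posterior(fit), kind == "derived")
#>        parameter    kind  mean    sd  q2.5 q97.5 rhat
#> 12         phi_1 derived 0.824 0.044 0.734  0.90    1
#> 13         phi_2 derived 0.821 0.057 0.703  0.93    1
#> 14       gamma_1 derived 0.086 0.053 0.013  0.21    1
#> 15       gamma_2 derived 0.077 0.041 0.016  0.17    1
#> 16         psi_1 derived 0.734 0.037 0.660  0.80    1
#> 17         psi_2 derived 0.629 0.042 0.545  0.71    1
#> 18         psi_3 derived 0.545 0.047 0.454  0.64    1
#> 19  lambda_total derived 0.742 0.060 0.626  0.86    1
#> 20 lambda_annual derived 0.861 0.035 0.791  0.93    1
```

The annual occurrence growth rate is estimated at 0.861 (95% CrI
0.79–0.93) against a generating value of 0.86: the credible interval lies
below 1, the "evidence of decline" verdict. Predictive performance and
residual structure:

```r
posterior_auc(fit, ds$data)
#> posterior AUC (year 3): 0.768 (95% CrI 0.730-0.803), 0/6000 draws skipped
moran_profile(fit, ds$data, seed = 1)
#>   threshold_km       I null_mean     p
#> 1           10 -0.1019  -0.00529 0.713
#> ...
```

No residual spatial autocorrelation at any threshold (all p > 0.05), as
expected for a spatially balanced design.

The full flow (simulate → fit under both prior regimes → evaluate →
report with manifest) is one call:

```r
pipeline_run(scenario_config(seed = 1), outdir = "run1")
```

or from a shell via `inst/cli/occutrend.R`.

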