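# thermofish

Hierarchical Bayesian analysis of how long-term whole-ecosystem warming
changes fish growth, mortality, and population size structure.

The package targets a two-population design: a fish population in an
artificially heated enclosed coastal basin versus its conspecific reference
population in the adjacent archipelago, sampled annually with survey
gillnets over ~two decades. It answers, on catch and growth-increment data
(or on synthetic data with the same statistical structure), four questions:

1. **Do fish grow to different sizes-at-age?** Von Bertalanffy growth,
   `L(t) = L∞(1 − e^(−K(t − t0)))`, fitted on log length with a Student-t
   likelihood and cohort-varying `L∞`, `K` around area hyper-means; all 8
   shared/area-specific variants, ranked by LOO-CV.
2. **Do growth rates differ across body sizes?** Specific growth
   `G = 100·(log L_{t+1} − log L_t)` from back-calculated lengths
   (`L_a = L_s (r_a/R)^s`, s = 0.861), modelled as `G = αL^θ` with
   individual-within-cohort effects on α.
3. **Is mortality higher?** Catch-curve regression: age-length keys expand
   binned catch to CPUE-at-age; on the descending limb,
   `log(CPUE) ~ age` has slope `−Z`; annual mortality is `1 − e^(−Z)`.
4. **How does the size/age structure differ?** A bounded power-law
   (MLEbin) size-spectrum exponent with profile-likelihood CI, and lognormal
   mean size/age models with correlated year-varying area intercepts.

Everything runs without external data: `simulate_cohorts()` /
`simulate_catch()` generate populations with cohort-varying growth,
exponential survival, dome-shaped gillnet selectivity, Student-t length
noise, and catch binned per net-night (2.5 cm classes; 1 cm in late years).
Because the environment provides no Stan/brms/loo, the package ships its own
adaptive MCMC engine (Rcpp), split-R̂ diagnostics, and PSIS-LOO — validated
in the test suite against closed-form conjugate posteriors, OLS limits, and
exact leave-one-out.

## Worked example

```r
library(thermofish)

cfg <- pipeline_config(
  sim     = sim_config(recruits_per_cohort = 300),  # stated-world defaults
  sampler = sampler_config(chains = 3, iter = 2000),
  n_aged_per_area = 400,
  seed = 1
)
res <- run_pipeline(cfg)
print(res)
```

```
thermofish pipeline report (seed 1)
  Linf percent difference (heat-ref): 20.155 %
  K percent difference (heat-ref):   15.5 %
  alpha percent difference:          10.722 %
  P(alpha_heat - alpha_ref < 0):     0.317
  Z heated / reference:              0.78 0.569 1/yr
  annual mortality heated/reference: 0.542 0.434
  size-spectrum gamma heated/ref:    -1.051 -0.793
  mean size difference (heat-ref):   1.776 cm
  mean age difference (heat-ref):    -1.072 yr
```


Reading the report: at this reduced demo size the heated population reaches a
~20% larger asymptotic length and a ~16% larger growth coefficient (the
generating truth is 16% and 27%); size-specific growth is ~11% faster (truth
18%, weakly resolved at this subsample size, hence the 0.32 posterior mass
below zero); total mortality is higher in the heated area (0.78 vs 0.57 per
year, i.e. 54% vs 43% dying annually; truth 0.73/0.62); and despite dying
younger (−1.1 yr mean age), heated fish are on average 1.8 cm longer —
faster growth outpacing the extra mortality. Larger simulations (see
`tests/testthat/test-acceptance.R`) recover the generating parameters within
10%.

Individual stages are available as plain functions (`fit_vbge()`,
`growth_observations()`, `build_alk()`, `expand_catch()`,
`select_descending_limb()`, `fit_catch_curve()`, `mlebin_fit()`,
`fit_lognormal()`, `loo_compare()`, ...), and a thin command-line wrapper
with the same stages lives at `inst/cli/thermofish`. See the methods
vignette (`vignettes/thermofish-methods.Rmd`) for the model definitions,
priors, sampler design, and the synthetic world's assumptions.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
simulating the heated and reference populations, fitting every stage, and
printing the report above — and writes its JSON output:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
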