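---
title: "Models and methods in thermofish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in thermofish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

`thermofish` analyses how more than two decades of whole-ecosystem heating
change the life history of an unexploited fish population. The design it
targets is a pair of reproductively isolated populations of the same species:
one in an artificially heated enclosed basin (5--10 °C above ambient), one in
an adjacent reference area, sampled annually with survey gillnets. Four
population quantities are compared between the areas:

1. **size-at-age**, through a hierarchical von Bertalanffy growth model;
2. **size-specific growth rate**, through an allometric model on
   back-calculated lengths-at-age;
3. **total mortality** `Z`, through catch-curve regression on age-length-key
   expanded catch-per-unit-effort (CPUE);
4. **population size and age structure**, through a bounded power-law size
   spectrum and lognormal mean size/age models.

All models are Bayesian, fitted with the package's own adaptive MCMC engine,
checked with split-$\hat R$ and posterior predictive checks, and compared by
PSIS-LOO.

# The models

## Growth in length at age

Length at catch is modelled on the natural-log scale with a Student-t
likelihood for robustness to aberrant readings:

$$\log L_i \sim \mathrm{Student}\text{-}t\big(\nu,\;
\log[L_{\infty j}(1 - e^{-K_j (t_i - t_0)})],\; \sigma\big)$$

$L_\infty$ (asymptotic length, cm) and $K$ (Brody coefficient, 1/yr) vary by
cohort $j$ around area-level hyper-means, with independent normal deviations
(no cross-parameter correlation is modelled) and area-specific between-cohort
SDs. $t_0$ is a per-area fixed effect: the cohort distribution covers only
$L_\infty$ and $K$, and letting $t_0$ wander by cohort is neither
identifiable at ~30--60 fish per cohort nor part of the hierarchical prior.
Each of $L_\infty$, $K$, $t_0$ may be shared between areas or area-specific,
giving 8 variants (`vbge_variants()`); variants are ranked by LOO-CV.

Only age and length *at catch* enter this model (one observation per fish),
not back-calculated lengths; within-individual correlation would otherwise
have to be modelled as well.

Priors: $\mu_{L_\infty} \sim N(45, 20)$ cm, $\mu_K \sim N(0.2, 0.1)$ 1/yr,
$t_0 \sim N(-0.5, 1)$ yr, $\nu \sim \mathrm{Gamma}(2, 0.1)$, all scales
half-Student-t(3, 0, 2.5). These are informative enough to keep the
non-linear model identified, and prior predictive draws
(`prior_predictive_vbge()`) give positive, biologically plausible lengths.
Positivity of $L_\infty$ and $K$ is enforced by sampling the hyper-means on
the log scale (the stated natural-scale priors are applied through a change
of variables) and rejecting proposals that imply a non-positive mean length.

## Allometric growth

Annual specific growth $G = 100(\log L_{t+1} - \log L_t)$ (%/yr, natural
logs), computed from back-calculated lengths, declines with the geometric
mean length $L = \sqrt{L_t L_{t+1}}$ as $G = \alpha L^\theta$. The initial
growth $\alpha$ (the curve's level at 1 cm) carries nested random effects —
individual within cohort — and is always area-specific; $\theta$ is either
shared or area-specific (the two variants compared by LOO). Priors:
$\mu_\alpha \sim N(500, 100)$, $\theta \sim N(-1.2, 0.3)$, scales
half-Student-t(3, 0, 13.3), Student-t likelihood.

Back-calculation uses the power law between fish length and operculum radius,
$L = \kappa R^s$, giving $L_a = L_s (r_a / R)^s$ with $s = 0.861$; $\kappa$
cancels and is needed only by the simulator to invert the relation.

## Mortality

Under exponential decline $N_t = N_0 e^{-Zt}$ and catch proportional to
abundance, $\log(\mathrm{CPUE})$ is linear in age with slope $-Z$. Binned
catch is converted to catch-at-age with area-specific age-length keys (row
proportions of age given 2.5 cm length class, estimated from the aged
subsample), divided by effort in net-nights. Because gillnets undersample
small fish, only the descending limb is informative: ages at and beyond the
modal age of year-pooled mean CPUE per area (the paper-level practice; the
modal-age criterion is our explicit convention, recorded in the output).

The regression `log(CPUE) ~ heat + ref + age + age:heat` (Student-t
likelihood) allows group-varying coefficients under a correlated
multivariate-normal prior: all four coefficients (`cohort_effects = "full"`),
only the intercepts (`"intercept"`), or none. Grouping can be cohort
(`year - age`) or year; both readings appear in the source description and
are left to LOO. Flat priors on the coefficients, half-Student-t(3, 0, 2.5)
scales, and uniform partial correlations via a tanh transform (for two
varying coefficients this is exactly the LKJ(1) prior; for four it is a
close, proper stand-in — the environment provides no LKJ machinery).
$Z_{ref} = -\beta_2$, $Z_{heat} = -(\beta_2 + \beta_3)$; annual mortality is
$1 - e^{-Z}$.

## Size spectrum

The individual size distribution is modelled as a bounded power law
$f(x) \propto x^b$ on $[x_{min}, x_{max}]$ (body mass, g). The exponent is
estimated from binned counts by maximizing the exact multinomial likelihood
of the bin probabilities (the MLEbin approach) — not from bin midpoints or
regression, which are known to be biased. The 95% CI is the profile
likelihood set at $\log\mathcal L_{max} - 1.92$. All years are pooled before
fitting; 1 cm class years are first converted to the 2.5 cm standard by
width-overlap allocation, and length classes map to mass bins through a
configurable length-weight law $W = aL^b$ (defaults $a = 0.01$, $b = 3$ are
generic artifact values, not estimates — the source does not print its
conversion). The fitted exponent is reported as $\gamma$; the biomass
spectrum convention is $b + 1$ and is recorded alongside.

## Mean size and age

The full catch (no descending-limb filter, since catchability with respect to
size is assumed equal between areas) is modelled as
$y \sim \mathrm{LogNormal}(\mu_i, \sigma)$ with per-area intercepts varying
by year under a correlated bivariate normal (`re = "area"`), or a single
shared year effect (`re = "common"`); the reading of "with and without random
slopes" as these two year-effect structures is our design choice — the mean
model contains no continuous covariate to carry a slope. Lengths enter as
class midpoints weighted by counts; ages as ALK-expanded ages weighted by
CPUE (frequency weights, equivalent to row replication at integer weights).
Area means on the cm/yr scale use the lognormal identity
$E[y] = e^{\mu + \sigma^2/2}$ with year effects omitted (the global
expectation); the posterior-predictive difference is necessarily wider than
this expected-value difference, and the package asserts that ordering.

# Inference engine

No Stan/brms/loo stack is available in the target environment, so the
machinery is part of the package:

* **Sampler.** Adaptive Metropolis-within-Gibbs in C++: coordinate-wise
  Gaussian proposals tuned to 0.44 acceptance during warmup, with only the
  observations a coordinate touches re-evaluated. Three additions deal with
  the posterior geometries these models produce: (i) adaptive multivariate
  block updates (covariance learned during warmup, scaled $2.38^2/d$) over
  the global parameters, each area's hyper-parameters, and each cohort's
  $(z_{L_\infty}, z_K)$ pair — the growth-curve trade-off ridge; (ii)
  likelihood-invariant "shift" and "rescale" moves that slide a hyper-mean or
  group SD while moving its non-centered deviations to keep group-level
  values fixed (only priors and an exact Jacobian enter the acceptance
  ratio), which breaks the slow coupling between hyper-parameters and
  deviations; (iii) a mid-warmup reset of the block covariance estimates so
  pre-convergence history does not contaminate them.
* **Contract.** 3 chains, 4000 iterations per chain with the first half as
  warmup by default ("iterations in total" is read as including warmup; the
  source does not state the split). These are random-walk chains: for the
  non-linear growth models the recovery analyses run longer chains and *thin*
  to the target number of stored draws — an honest way to reach the stated
  draw counts at $\hat R < 1.1$ with a random-walk kernel.
* **Diagnostics.** Classic split-$\hat R$ per parameter; a fit with any
  $\hat R \ge 1.1$ is flagged as non-converged (`check_convergence()`), not
  silently accepted — mirroring the upstream observation that fully shared
  growth variants fail to converge.
* **LOO.** PSIS-LOO from the pointwise log-likelihood matrix: importance
  ratios Pareto-smoothed with the Zhang–Stephens empirical-Bayes generalized
  Pareto fit (weakly regularized towards shape 0.5), per-observation shape
  $k$ reported, warning at $k \ge 0.7$. Validated in the tests against exact
  closed-form leave-one-out for a conjugate normal model.
* **Predictive checks.** Replicates are simulated through an R
  re-implementation of each model's mean structure, which doubles as an
  independent oracle of the compiled likelihoods in the test suite.

# The synthetic world

The generator (`sim_config()`, `simulate_cohorts()`, `simulate_catch()`)
emulates the study system; its defaults *are* the stated conditions:
hyper-means at the reported posterior medians ($L_\infty$ 45.7/39.4 cm, $K$
0.19/0.15, $t_0 = -0.5$), $Z$ 0.73/0.62 1/yr, $\alpha$ 512/433, $\theta$
−1.13/−1.18, $s = 0.861$, cohorts 1981--1997, catch years 1987--2003 with
1 cm classes in 2001--2003. Values the source does not print were fixed once
at field-realistic levels and are not revisited:

* between-cohort SDs 3 cm ($L_\infty$) and 0.02 ($K$) — of the order of the
  cohort scatter visible in the study's cohort-level estimates;
* observation noise: Student-t($\nu = 10$) with scale 0.05 on log length
  (≈5% length error, mildly heavy-tailed);
* specific-growth noise $\sigma_G = 10$ %/yr with nested SDs 25 (cohort) and
  50 (individual) — consistent with the half-t(3, 0, 13.3) prior scale the
  source chose for these variances;
* dome-shaped selectivity: lognormal in length, mode 20 cm, spread 0.4 (any
  unimodal curve exercises the descending-limb logic; the mesh structure is
  unknown);
* $\kappa = 8$ (arbitrary positive; cancels in back-calculation), 16
  net-nights per area-year, 200 recruits per cohort by default.

Deaths fall between birthdays, so ages are integers and annual survival is
exactly $e^{-Z}$; radii come from exact inversion of the back-calculation
power law at true birthday lengths (optional multiplicative jitter, default
off, keeps the round-trip test exact). The aged subsample in
`simulate_growth_data()` and the pipeline is *length-stratified*, as in the
survey practice: the age distribution of aged fish is much flatter than raw
survival (~5 increments per fish) and the age-length key covers every catch
class.

What the generator does **not** emulate: spatial structure or migration,
males (the study uses females only), density dependence, year-to-year
temperature variation, multi-species interactions. A green recovery test
therefore establishes that the estimators recover the parameters of this
stated world at realistic sample sizes — not that the real system satisfies
the models.

# Numerical choices and edge cases

* The PLB bin probability uses the closed form in $b + 1$ with an explicit
  log-form branch within $10^{-8}$ of $b = -1$; probabilities over a full
  span sum to 1 to $10^{-12}$.
* `expand_catch()` conserves totals exactly (row-normalized keys); a catch
  class missing from the key borrows the nearest class within one class
  width, further gaps are an error naming the class.
* Zero-CPUE rows are dropped (with a message) before logs; an area with
  fewer than 3 distinct ages is an error (slope unidentifiable).
* Ties and single-fish cohorts are retained; the hierarchy shrinks them.
* `percent_difference()` drops division-by-zero draws with a warning.
* Noiseless data drive $\sigma \to 0$; conditional on any $\sigma$ the
  coefficient posterior is symmetric about the least-squares solution, so
  medians recover exact slopes to 4+ decimals even though $\sigma$'s own
  chain keeps drifting downward (its $\hat R$ is meaningless in that
  degenerate case).

# Known limitations

* Single-run credible-interval coverage is itself a ~90% event per
  parameter; the recovery checks use fixed seeds and study-scale data so the
  posterior is tight and centred, but coverage of every parameter in every
  replicate is not a mathematical guarantee.
* The plug-in ratio of heated to reference size-at-age at the reported
  posterior medians is 1.19--1.43 across ages — the reported 7--11% band is a
  property of the full posterior of the real data, not of the medians — so
  end-to-end checks assert the *direction* of the size-at-age contrast, not
  that band.
* $\alpha$ is an extrapolation of the growth curve to 1 cm, far below the
  observed lengths; its posterior trades off strongly with $\theta$, which
  is why study-scale sample sizes are needed for tight recovery.
* The MLEbin fit treats CPUE-weighted counts as multinomial weights; it does
  not propagate effort uncertainty.
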