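# Shared fixtures: small stated-world configurations kept fast enough for the
# unit suite. Heavy recovery runs live in test-acceptance.R.

small_sim <- function(seed = 1, ...) {
  sim_config(recruits_per_cohort = 100L, seed = seed, ...)
}

quick_mcmc <- function(chains = 3L, iter = 1000L, ...) {
  sampler_config(chains = chains, iter = iter, ...)
}

# deterministic tiny catch-at-age table with exact exponential decline
exact_caa <- function(Z = 0.7, ages = 2:6, q = 1000, area = "ref",
                      year = 2000) {
  data.frame(area = area, year = year, age = ages, cpue = q * exp(-Z * ages))
}
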