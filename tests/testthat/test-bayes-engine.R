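# Inference machinery: split-R-hat, PSIS-LOO against the analytic conjugate
# oracle, model comparison bookkeeping, and predictive checks.

fake_fit <- function(arr, pars = dimnames(arr)[[3]]) {
  structure(list(draws = arr, pars = pars,
                 rhat = apply(arr, 3, thermofish:::split_rhat)),
            class = "tf_fit")
}

test_that("split-R-hat is ~1 for mixed chains and large for separated ones", {
  set.seed(71)
  good <- array(rnorm(4000 * 3), c(4000, 3, 1), dimnames = list(NULL, NULL, "a"))
  bad <- array(c(rnorm(2000, 0), rnorm(2000, 10)), c(2000, 2, 1),
               dimnames = list(NULL, NULL, "a"))
  f_good <- fake_fit(good)
  f_bad <- fake_fit(bad)
  expect_lt(check_convergence(f_good)$rhat[["a"]], 1.02)
  expect_true(check_convergence(f_good)$pass)
  expect_gt(check_convergence(f_bad)$rhat[["a"]], 3)
  expect_false(check_convergence(f_bad)$pass)
  expect_equal(check_convergence(f_bad)$failed, "a")
  # single chain errors; report lists every parameter exactly once
  one <- array(rnorm(100), c(100, 1, 2), dimnames = list(NULL, NULL, c("a", "b")))
  expect_error(check_convergence(fake_fit(one)), "2 chains")
  two <- array(rnorm(400), c(100, 2, 2), dimnames = list(NULL, NULL, c("a", "b")))
  expect_equal(names(check_convergence(fake_fit(two))$rhat), c("a", "b"))
})

test_that("generalized Pareto tail fit recovers known shapes", {
  set.seed(72)
  qg <- function(u, k, s) s / k * ((1 - u)^(-k) - 1)
  x1 <- qg(runif(3000), 0.4, 1)
  expect_equal(thermofish:::gpd_fit(x1)$k, 0.4, tolerance = 0.08)
  x2 <- rexp(3000)  # k = 0 limit
  expect_lt(abs(thermofish:::gpd_fit(x2)$k), 0.08)
})

test_that("PSIS-LOO matches exact leave-one-out for the conjugate normal", {
  set.seed(73)
  n <- 50; s <- 1; tau2 <- 100
  y <- rnorm(n, 1.3, s)
  # exact LOO predictive: y_i | y_-i ~ N(m_-i, s^2 + v_-i)
  exact <- vapply(seq_len(n), function(i) {
    yi <- y[-i]
    v <- 1 / (length(yi) / s^2 + 1 / tau2)
    m <- v * sum(yi) / s^2
    dnorm(y[i], m, sqrt(s^2 + v), log = TRUE)
  }, 0)
  # posterior draws of mu given all data
  v_n <- 1 / (n / s^2 + 1 / tau2)
  m_n <- v_n * sum(y) / s^2
  mu <- rnorm(8000, m_n, sqrt(v_n))
  ll <- vapply(seq_len(n), function(i) dnorm(y[i], mu, s, log = TRUE),
               numeric(8000))
  res <- loo(ll)
  expect_equal(res$elpd, sum(exact), tolerance = 0.5)
  expect_lt(max(res$k), 0.7)
  expect_gt(res$p_loo, 0.5)  # about one effective parameter
  expect_lt(res$p_loo, 2)
})

test_that("loo_compare ranks models and is exact for self-comparison", {
  set.seed(74)
  y <- rnorm(40, 2, 1)
  mu <- rnorm(4000, mean(y), 1 / sqrt(40))
  ll_good <- vapply(seq_along(y), function(i) dnorm(y[i], mu, 1, log = TRUE),
                    numeric(4000))
  ll_bad <- vapply(seq_along(y), function(i) dnorm(y[i], mu - 3, 1, log = TRUE),
                   numeric(4000))
  l1 <- loo(ll_good)
  cmp <- loo_compare(good = l1, self = l1, bad = loo(ll_bad))
  expect_equal(cmp$elpd_diff[cmp$model == "self"], 0)
  expect_equal(cmp$model[3], "bad")
  expect_lt(cmp$elpd_diff[3], -50)
  # mismatched observation sets error
  expect_error(loo_compare(l1, loo(ll_bad[, 1:10])), "different numbers")
})

test_that("prior predictive lengths are positive and finite", {
  set.seed(75)
  L <- prior_predictive_vbge(1000, ages = 1:10)
  expect_gt(mean(L > 0 & is.finite(L)), 0.99)
  # and broadly plausible in scale: medians within an order of magnitude
  expect_true(median(L) > 1 && median(L) < 200)
})

test_that("posterior predictive checks are calibrated and detect heavy tails", {
  set.seed(76)
  cfgm <- quick_mcmc(chains = 2, iter = 800)
  ok <- 0
  for (rep in 1:5) {
    d <- data.frame(y = rlnorm(150, 3, 0.3), area = "ref",
                    year = rep(2000:2004, 30))
    f <- fit_lognormal(d, re = "common", config = cfgm)
    p <- predictive_check(f, statistic = mean, ndraws = 200)
    if (p$p >= 0.05 && p$p <= 1) ok <- ok + 1
  }
  expect_gte(ok, 4)  # well-specified model: mean is not extreme
  # contaminated data under a lognormal model: the maximum is extreme
  ly <- c(rnorm(297, 3, 0.2), rnorm(3, 6, 0.2))
  d2 <- data.frame(y = exp(ly), area = "ref", year = rep(2000:2004, 60))
  f2 <- fit_lognormal(d2, re = "common", config = cfgm)
  p2 <- predictive_check(f2, statistic = max, ndraws = 200)
  expect_lt(p2$p, 0.2)
})

test_that("compiled likelihoods agree with the R reference implementation", {
  set.seed(77)
  cfg <- small_sim(seed = 77)
  fish <- simulate_cohorts(cfg)
  aged <- fish[sample(nrow(fish), 200), ]
  fits <- list(
    fit_vbge(aged, config = quick_mcmc(chains = 2, iter = 200)),
    fit_allometric_growth(simulate_growth_data(cfg, 40),
                          config = quick_mcmc(chains = 2, iter = 200)),
    fit_catch_curve(simulate_catch_at_age(cfg, years = 8),
                    cohort_effects = "full", group = "cohort",
                    config = quick_mcmc(chains = 2, iter = 200)),
    fit_lognormal(data.frame(y = rlnorm(100, 3, 0.2), w = rpois(100, 3) + 1,
                             area = rep(c("heat", "ref"), 50),
                             year = rep(2000:2004, 20)),
                  config = quick_mcmc(chains = 2, iter = 200))
  )
  for (fit in fits) {
    idx <- sample(nrow(fit$raw), 5)
    ll_cpp <- thermofish:::.model_loglik(fit$model, fit$data,
                                         fit$raw[idx, , drop = FALSE])
    ll_ref <- t(sapply(idx, function(s)
      thermofish:::model_loglik_ref(fit, fit$raw[s, ])))
    expect_equal(ll_cpp, ll_ref, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("sampler matches the analytic posterior on a linear model", {
  # noisy single-area catch curve: flat priors, so the conditional posterior
  # of the slope is centred at the OLS estimate
  set.seed(78)
  ages <- rep(2:7, 10)
  caa <- data.frame(area = "ref", year = 2000L, age = ages,
                    cpue = exp(7 - 0.65 * ages + rnorm(length(ages), 0, 0.2)))
  fit <- fit_catch_curve(caa, cohort_effects = "none",
                         config = quick_mcmc(iter = 3000), seed = 4)
  ols <- coef(lm(log(cpue) ~ age, data = caa))
  expect_equal(median(posterior_draws(fit, "b_age")), unname(ols[2]),
               tolerance = 0.01)
  expect_equal(median(posterior_draws(fit, "b_int_ref")), unname(ols[1]),
               tolerance = 0.05)
})

test_that("diagnostics are pure functions of draws: same seed, same report", {
  caa <- exact_caa(Z = 0.5)
  f1 <- fit_catch_curve(caa, cohort_effects = "none",
                        config = quick_mcmc(chains = 2, iter = 400), seed = 12)
  f2 <- fit_catch_curve(caa, cohort_effects = "none",
                        config = quick_mcmc(chains = 2, iter = 400), seed = 12)
  expect_identical(f1$draws, f2$draws)
  expect_identical(check_convergence(f1), check_convergence(f2))
})
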