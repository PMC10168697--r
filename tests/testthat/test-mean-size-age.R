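# Lognormal mean size/age models and the natural-scale mean differences.

test_that("lognormal mean identity exp(mu + sigma^2/2) matches sample means", {
  set.seed(91)
  mu <- 3.1; s <- 0.4
  y <- rlnorm(200000, mu, s)
  expect_equal(mean(y), exp(mu + s^2 / 2), tolerance = 0.01)
})

test_that("closed-form mean difference from point draws", {
  # mu_heat = mu_ref + delta, common sigma:
  # difference = exp(mu_ref + s^2/2) * (exp(delta) - 1)
  mu <- log(20); delta <- 0.1; s <- 0.3
  arr <- array(rep(c(mu + delta, mu, s), each = 20), c(10, 2, 3),
               dimnames = list(NULL, NULL, c("b_heat", "b_ref", "sigma")))
  fit <- structure(list(draws = arr, pars = dimnames(arr)[[3]],
                        spec = list(model = "lnorm"),
                        rhat = rep(1, 3)),
                   class = "tf_fit")
  pm <- posterior_mean_difference(fit)
  expect_equal(pm$median, exp(mu + s^2 / 2) * (exp(delta) - 1),
               tolerance = 1e-12)
  # identical area parameters: difference centred at 0
  arr0 <- arr; arr0[, , "b_heat"] <- mu
  fit0 <- structure(list(draws = arr0, pars = dimnames(arr0)[[3]],
                         spec = list(model = "lnorm"), rhat = rep(1, 3)),
                    class = "tf_fit")
  expect_equal(posterior_mean_difference(fit0)$median, 0)
})

test_that("degenerate lognormal: all values c recover mean c", {
  set.seed(92)
  d <- data.frame(y = rep(17.3, 120), area = "ref",
                  year = rep(2000:2002, 40))
  fit <- fit_lognormal(d, re = "common",
                       config = quick_mcmc(chains = 2, iter = 1000))
  pm <- posterior_mean_difference(fit)
  expect_equal(median(pm$mean_ref), 17.3, tolerance = 0.02)
})

test_that("two-area recovery: ~2 cm difference, sign flips on relabeling", {
  set.seed(93)
  n <- 1200
  s <- 0.2
  d <- data.frame(
    y = c(rlnorm(n, log(22) - s^2 / 2, s), rlnorm(n, log(20) - s^2 / 2, s)),
    area = rep(c("heat", "ref"), each = n),
    year = sample(1987:2003, 2 * n, TRUE))
  cfgm <- quick_mcmc(chains = 2, iter = 2000)
  fit <- fit_lognormal(d, config = cfgm, seed = 5)
  pm <- posterior_mean_difference(fit)
  expect_equal(pm$median, 2, tolerance = 0.35)
  expect_true(pm$l95 < 2 + 0.5 && pm$u95 > 2 - 0.5)
  sw <- d; sw$area <- ifelse(d$area == "heat", "ref", "heat")
  fit2 <- fit_lognormal(sw, config = cfgm, seed = 5)
  pm2 <- posterior_mean_difference(fit2)
  expect_equal(pm2$median, -pm$median, tolerance = 0.3)
})

test_that("expected-value difference is narrower than predictive difference", {
  set.seed(94)
  d <- data.frame(y = rlnorm(400, 3, 0.3),
                  area = rep(c("heat", "ref"), 200),
                  year = rep(1990:1999, 40))
  fit <- fit_lognormal(d, config = quick_mcmc(chains = 2, iter = 1000))
  ev <- posterior_mean_difference(fit)$draws
  pp <- posterior_predictive_difference(fit)
  expect_lt(var(ev), var(pp))
})

test_that("nonpositive responses and bad weights error", {
  d <- data.frame(y = c(1, -2), area = c("heat", "ref"), year = 2000L)
  expect_error(fit_lognormal(d), "positive")
  d2 <- data.frame(y = c(1, 2), w = c(1, -1), area = c("heat", "ref"),
                   year = 2000L)
  expect_error(fit_lognormal(d2), "nonnegative")
})

test_that("catch_responses builds weighted midpoint/age tables", {
  catch <- data.frame(area = "heat", year = 2000L, net_id = 1L,
                      length_class_lower = c(10, 12.5),
                      length_class_width = 2.5, count = c(3, 0))
  cr <- catch_responses(catch = catch, response = "length")
  expect_equal(cr$y, 11.25)  # zero-count class dropped, midpoint used
  expect_equal(cr$w, 3)
  caa <- data.frame(area = "ref", year = 2001L, age = c(2L, 3L),
                    cpue = c(1.5, 0))
  ca <- catch_responses(catch_at_age = caa, response = "age")
  expect_equal(ca$y, 2)
  expect_equal(ca$w, 1.5)
})
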