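# Growth model surface: mean functions, contrasts, predictions, variants.

test_that("the VBGE mean function matches the closed form", {
  # at the heated-area posterior medians, age 3: 45.7*(1-exp(-0.19*3.5))
  expect_equal(vbge_length(3, 45.7, 0.19, -0.5), 22.1977, tolerance = 1e-4)
  expect_equal(vbge_length(-0.5, 45.7, 0.19, -0.5), 0)  # root at t = t0
  expect_true(all(diff(vbge_length(1:30, 40, 0.2, -0.5)) > 0))
})

test_that("percent contrasts reproduce the printed study differences", {
  # asymptotic length: (45.7 - 39.4) / 39.4 -> 16%
  expect_equal(round(percent_difference(45.7, 39.4)$median), 16)
  # growth coefficient: (0.19 - 0.15) / 0.15 -> 27%
  expect_equal(round(percent_difference(0.19, 0.15)$median), 27)
  # initial growth: (512 - 433) / 433 -> 18%
  expect_equal(round(percent_difference(512, 433)$median), 18)
  # identical draws: 0 with a zero-width interval
  x <- rnorm(100, 10)
  pd <- percent_difference(x, x)
  expect_equal(pd$median, 0)
  expect_equal(pd$l95, 0)
  expect_equal(pd$u95, 0)
  expect_error(percent_difference(1:3, 1:2), "equal length")
  expect_warning(percent_difference(c(1, 2), c(0, 2)), "division-by-zero")
})

test_that("prob_below_zero is the Monte-Carlo tail mass", {
  expect_equal(prob_below_zero(c(1, 2, 3)), 0)
  set.seed(81)
  expect_equal(prob_below_zero(rnorm(20000)), 0.5, tolerance = 0.02)
  # shifted normal: P(X < 0) = pnorm(-2)
  expect_lt(abs(prob_below_zero(rnorm(20000, 2, 1)) - 0.02275), 0.007)
  expect_error(prob_below_zero(numeric(0)), "empty")
})

test_that("exactly 8 VBGE variants and 2 allometric variants exist", {
  v <- vbge_variants()
  expect_length(v, 8L)
  expect_equal(nrow(unique(do.call(rbind, v))), 8L)
  expect_true(all(vapply(v, function(x)
    identical(names(x), c("Linf", "K", "t0")), TRUE)))
})

test_that("size-at-age prediction is the plug-in curve at point draws", {
  arr <- array(rep(c(45.7, 0.19, -0.5), each = 20), c(10, 2, 3),
               dimnames = list(NULL, NULL, c("mu_Linf", "mu_K", "t0")))
  fit <- structure(list(draws = arr, pars = dimnames(arr)[[3]],
                        spec = list(model = "vbge", age_range = c(1, 10)),
                        rhat = c(mu_Linf = 1, mu_K = 1, t0 = 1)),
                   class = "tf_fit")
  pred <- predict_size_at_age(fit, 1:5, "heat")
  expect_equal(pred$median, vbge_length(1:5, 45.7, 0.19, -0.5))
  expect_equal(pred$l90, pred$u90)  # degenerate draws: zero-width intervals
  expect_false(any(pred$extrapolated))
  expect_warning(p2 <- predict_size_at_age(fit, c(5, 30), "heat"),
                 "extrapolates")
  expect_equal(p2$extrapolated, c(FALSE, TRUE))
})

test_that("fit_vbge validates its inputs", {
  fish <- simulate_cohorts(small_sim(seed = 82))
  one_cohort <- fish[fish$cohort == fish$cohort[1], ]
  expect_error(fit_vbge(one_cohort), ">= 2 cohorts")
  bad <- fish[1:50, ]; bad$area <- "north"
  expect_error(fit_vbge(bad), "heat")
})

test_that("relabeling areas swaps the fitted area posteriors", {
  set.seed(83)
  cfg <- sim_config(recruits_per_cohort = 250L, seed = 83)
  fish <- simulate_cohorts(cfg)
  aged <- fish[sample(nrow(fish), 600), ]
  sw <- aged
  sw$area <- ifelse(aged$area == "heat", "ref", "heat")
  cfgm <- quick_mcmc(chains = 2, iter = 3000)
  f1 <- fit_vbge(aged, config = cfgm, seed = 19)
  f2 <- fit_vbge(sw, config = cfgm, seed = 19)
  m1 <- summary(f1); m2 <- summary(f2)
  expect_equal(m1$median[m1$parameter == "mu_Linf[heat]"],
               m2$median[m2$parameter == "mu_Linf[ref]"], tolerance = 0.05)
  expect_equal(m1$median[m1$parameter == "mu_K[ref]"],
               m2$median[m2$parameter == "mu_K[heat]"], tolerance = 0.05)
})

test_that("predicted size-at-age is larger in the faster-growing area", {
  set.seed(84)
  cfg <- sim_config(recruits_per_cohort = 250L, seed = 84)
  fish <- simulate_cohorts(cfg)
  aged <- fish[sample(nrow(fish), 600), ]
  fit <- fit_vbge(aged, config = quick_mcmc(chains = 2, iter = 3000), seed = 2)
  ages <- 1:10
  ph <- predict_size_at_age(fit, ages, "heat")
  pr <- predict_size_at_age(fit, ages, "ref")
  expect_true(all(ph$median > pr$median))
})
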