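# The synthetic-data generators: bookkeeping identities, survival law,
# zero-noise limit, binning, conservation and determinism.

test_that("every record satisfies the fish invariants", {
  fish <- simulate_cohorts(small_sim(seed = 2))
  expect_true(all(fish$catch_year - fish$age == fish$cohort))
  expect_true(all(lengths(fish$radii) == fish$age))
  expect_true(all(fish$length_at_catch > 0))
  expect_true(all(vapply(fish$radii, function(r)
    length(r) == 1L || all(diff(r) > 0), TRUE)))
  expect_equal(nrow(validate_inputs(fish = fish)), 0L)
})

test_that("recruit bookkeeping: recruits x cohorts records before thinning", {
  cfg <- sim_config(recruits_per_cohort = 100L,
                    cohorts = 1990:1992, catch_years = 1987:2030,
                    seed = 5)
  fish <- simulate_cohorts(cfg, keep_all = TRUE)
  # 3 cohorts x 100 recruits x 2 areas, radii length equals age everywhere
  expect_equal(nrow(fish), 600L)
  expect_true(all(lengths(fish$radii) == fish$age))
})

test_that("survival thinning follows exp(-Z) per year", {
  Z <- 0.7
  cfg <- sim_config(Z = c(heat = Z, ref = Z), recruits_per_cohort = 10000L,
                    cohorts = 1990L, catch_years = 1900:2100, max_age = 50L,
                    seed = 8)
  fish <- simulate_cohorts(cfg, keep_all = TRUE)
  f <- fish[fish$area == "heat", ]
  # P(alive one extra year) = exp(-Z); binomial MC error at n = 10,000
  frac <- sum(f$age > 2) / sum(f$age > 1)
  expect_equal(frac, exp(-Z), tolerance = 0.03)
  frac2 <- sum(f$age > 4) / sum(f$age > 3)
  expect_equal(frac2, exp(-Z), tolerance = 0.06)
})

test_that("zero noise gives lengths exactly on the growth curve", {
  cfg <- sim_config(sigma_Linf = c(heat = 0, ref = 0),
                    sigma_K = c(heat = 0, ref = 0), sigma_obs = 0,
                    recruits_per_cohort = 50L, seed = 4)
  fish <- simulate_cohorts(cfg)
  for (a in c("heat", "ref")) {
    f <- fish[fish$area == a, ]
    expect_equal(f$length_at_catch,
                 vbge_length(f$age, cfg$mu_Linf[[a]], cfg$mu_K[[a]],
                             cfg$t0[[a]]),
                 tolerance = 1e-12)
  }
})

test_that("catch simulation conserves fish and bins to the grid", {
  cfg <- small_sim(seed = 6, nets_per_year = 4L)
  fish <- simulate_cohorts(cfg)
  catch <- simulate_catch(fish, cfg, selectivity = FALSE)
  # selectivity off: every fish lands in exactly one class of one net
  expect_equal(sum(catch$count), nrow(fish))
  expect_true(all(catch$length_class_width %in% c(1, 2.5)))
  off <- catch$length_class_lower / catch$length_class_width
  expect_equal(off, round(off))
  # late years use the 1 cm grid
  expect_true(all(catch$length_class_width[catch$year %in% cfg$years_1cm] == 1))
  expect_true(all(catch$length_class_width[!catch$year %in% cfg$years_1cm] == 2.5))
  expect_equal(nrow(validate_inputs(catch = catch[catch$length_class_width == 2.5, ])), 0L)
})

test_that("all fish of one length land in the containing 2.5 cm class", {
  fish <- data.frame(id = 1:40, area = "ref", cohort = 1990L,
                     catch_year = 1995L, age = 5L, length_at_catch = 11.3)
  cfg <- small_sim(seed = 1)
  catch <- simulate_catch(fish, cfg, selectivity = FALSE)
  expect_true(all(catch$length_class_lower == 10.0))
  expect_equal(sum(catch$count), 40L)
})

test_that("dome selectivity enriches lengths near the mode", {
  cfg <- sim_config(recruits_per_cohort = 2000L, sel_mode = 20,
                    cohorts = 1990:1991, catch_years = 1991:1995, seed = 9)
  fish <- simulate_cohorts(cfg)
  # population dominated by small (< 20 cm) fish
  expect_gt(mean(fish$length_at_catch < 20), 0.5)
  catch <- simulate_catch(fish, cfg, selectivity = TRUE)
  mid <- catch$length_class_lower + catch$length_class_width / 2
  mean_retained <- sum(mid * catch$count) / sum(catch$count)
  expect_gt(mean_retained, mean(fish$length_at_catch))
})

test_that("same seed gives identical tables; different seed differs", {
  cfg <- small_sim(seed = 42)
  f1 <- simulate_cohorts(cfg)
  f2 <- simulate_cohorts(cfg)
  expect_identical(f1, f2)
  set.seed(1); c1 <- simulate_catch(f1, cfg)
  set.seed(1); c2 <- simulate_catch(f1, cfg)
  expect_identical(c1, c2)
  f3 <- simulate_cohorts(small_sim(seed = 43))
  expect_false(identical(f1$length_at_catch, f3$length_at_catch))
})

test_that("incompatible cohort and catch windows error", {
  expect_error(
    simulate_cohorts(sim_config(cohorts = 2010:2012, catch_years = 1987:2003,
                                max_age = 25L, seed = 1)),
    "incompatible")
})

test_that("growth-data generator reproduces the allometric curve shape", {
  cfg <- sim_config(seed = 12, sigma_alpha_cohort = 0, sigma_alpha_id = 0,
                    sigma_G = 1e-9,
                    sigma_Linf = c(heat = 0, ref = 0),
                    sigma_K = c(heat = 0, ref = 0))
  obs <- simulate_growth_data(cfg, n_id_per_area = 30L)
  for (a in c("heat", "ref")) {
    o <- obs[obs$area == a, ]
    expect_equal(o$G, cfg$alpha[[a]] * o$L_geo^cfg$theta[[a]],
                 tolerance = 1e-6)
  }
})

test_that("catch-at-age generator declines at rate Z on average", {
  cfg <- sim_config(seed = 13)
  caa <- simulate_catch_at_age(cfg, years = 100, ages = 2:8,
                               sd_log = 0.1, sd_year = 0)
  for (a in c("heat", "ref")) {
    sl <- coef(lm(log(cpue) ~ age, data = caa[caa$area == a, ]))[2]
    expect_equal(unname(-sl), cfg$Z[[a]], tolerance = 0.02)
  }
  expect_true(all(caa$cohort + caa$age == caa$year))
})
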