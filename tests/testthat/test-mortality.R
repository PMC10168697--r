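# Age-length keys, catch-at-age expansion, descending limb, catch-curve
# regression and annual mortality.

test_that("ALK rows are conditional age proportions", {
  aged <- data.frame(length_at_catch = c(rep(11, 5)),
                     age = c(1, 1, 1, 1, 2), area = "ref")
  alk <- build_alk(aged)
  expect_equal(unname(alk$prop[1, ]), c(0.8, 0.2))
  # single age: identity-like key
  aged2 <- data.frame(length_at_catch = runif(30, 5, 30), age = 3, area = "ref")
  alk2 <- build_alk(aged2)
  expect_true(all(alk2$prop[!is.na(alk2$prop)] == 1))
  expect_error(build_alk(aged, area = "heat"), "no aged fish")
})

test_that("ALK rows sum to 1 and match true conditional proportions", {
  set.seed(31)
  # known age-length structure: age | class multinomial
  n <- 1000L
  classes <- c(10, 12.5, 15)
  probs <- rbind(c(0.7, 0.3, 0.0), c(0.2, 0.5, 0.3), c(0.05, 0.35, 0.6))
  rows <- list()
  for (k in seq_along(classes)) {
    ages <- sample(1:3, n, TRUE, prob = probs[k, ])
    rows[[k]] <- data.frame(length_at_catch = classes[k] + runif(n, 0, 2.4),
                            age = ages, area = "ref")
  }
  alk <- build_alk(do.call(rbind, rows))
  expect_equal(unname(rowSums(alk$prop)), rep(1, 3), tolerance = 1e-12)
  # binomial error at n = 1000 per class
  expect_equal(unname(alk$prop), unname(probs), tolerance = 0.05)
})

test_that("expansion distributes counts by the key and conserves fish", {
  alk <- structure(list(area = NULL, class_width = 2.5, classes = 10,
                        ages = 1:2, prop = matrix(c(0.8, 0.2), 1),
                        n = 50L), class = "tf_alk")
  catch <- data.frame(area = "ref", year = 2000L, net_id = 1L,
                      length_class_lower = 10, length_class_width = 2.5,
                      count = 50)
  caa <- expand_catch(catch, alk)
  expect_equal(caa$cpue, c(40, 10))
  expect_equal(caa$cohort, c(1999L, 1998L))
})

test_that("identity key relabels classes; totals conserved on random inputs", {
  set.seed(32)
  for (rep in 1:20) {
    ncls <- sample(3:8, 1)
    nage <- sample(2:6, 1)
    classes <- seq(10, by = 2.5, length.out = ncls)
    prop <- matrix(rgamma(ncls * nage, 1), ncls)
    prop <- prop / rowSums(prop)
    alk <- structure(list(area = NULL, class_width = 2.5, classes = classes,
                          ages = seq_len(nage), prop = prop,
                          n = rep(10L, ncls)), class = "tf_alk")
    catch <- data.frame(area = "ref", year = 2000L,
                        net_id = sample(1:3, ncls, TRUE),
                        length_class_lower = classes,
                        length_class_width = 2.5,
                        count = round(runif(ncls, 0, 200)))
    caa <- expand_catch(catch, alk)
    effort <- attr(caa, "effort")$effort
    expect_equal(sum(caa$cpue) * effort, sum(catch$count), tolerance = 1e-12)
  }
})

test_that("missing key class borrows the adjacent row or errors", {
  alk <- structure(list(area = NULL, class_width = 2.5, classes = c(10, 12.5),
                        ages = 1:2, prop = matrix(c(1, 0.5, 0, 0.5), 2),
                        n = c(10L, 10L)), class = "tf_alk")
  catch <- data.frame(area = "ref", year = 2000L, net_id = 1L,
                      length_class_lower = 15, length_class_width = 2.5,
                      count = 10)
  caa <- expand_catch(catch, alk)  # 15 borrows the 12.5 row
  expect_equal(caa$cpue, c(5, 5))
  catch$length_class_lower <- 25
  expect_error(expand_catch(catch, alk), "no adjacent neighbour")
})

test_that("descending limb keeps the modal age and older", {
  caa <- data.frame(area = "ref", year = 2000L, age = 1:5,
                    cpue = c(1, 5, 9, 4, 2))
  out <- select_descending_limb(caa)
  expect_equal(out$age, 3:5)
  expect_equal(unname(attr(out, "modal_age")), 3)
  # strictly decreasing CPUE keeps everything
  caa2 <- data.frame(area = "ref", year = 2000L, age = 1:5,
                     cpue = c(9, 7, 5, 3, 1))
  expect_equal(nrow(select_descending_limb(caa2)), 5L)
  expect_error(select_descending_limb(transform(caa, cpue = 0)), "zero")
})

test_that("noiseless exponential CPUE recovers the slope to 4 decimals", {
  caa <- exact_caa(Z = 0.7)
  fit <- fit_catch_curve(caa, cohort_effects = "none",
                         config = quick_mcmc(iter = 2000), seed = 17)
  Z <- mortality_Z(fit)
  expect_equal(median(Z$Z_ref), 0.7, tolerance = 1e-4)
  # frequentist cross-check is exact
  expect_equal(unname(catch_curve_lm(caa)), 0.7, tolerance = 1e-12)
})

test_that("area relabeling swaps the Z estimates", {
  cfg <- sim_config(seed = 51)
  caa <- simulate_catch_at_age(cfg, years = 15, ages = 2:8)
  sw <- caa
  sw$area <- ifelse(caa$area == "heat", "ref", "heat")
  cfgm <- quick_mcmc(iter = 2000)
  f1 <- fit_catch_curve(caa, cohort_effects = "none", config = cfgm, seed = 3)
  f2 <- fit_catch_curve(sw, cohort_effects = "none", config = cfgm, seed = 3)
  Z1 <- mortality_Z(f1); Z2 <- mortality_Z(f2)
  expect_equal(median(Z1$Z_heat), median(Z2$Z_ref), tolerance = 0.02)
  expect_equal(median(Z1$Z_ref), median(Z2$Z_heat), tolerance = 0.02)
})

test_that("zero CPUE rows are dropped with a message; few ages error", {
  caa <- rbind(exact_caa(), data.frame(area = "ref", year = 2000L, age = 7L,
                                       cpue = 0))
  expect_message(fit_catch_curve(caa, cohort_effects = "none",
                                 config = quick_mcmc(chains = 2, iter = 200)),
                 "dropping 1")
  expect_error(fit_catch_curve(exact_caa(ages = 2:4)[1:2, ]), "unidentifiable")
})

test_that("annual mortality matches the printed study values", {
  # 1 - exp(-Z) at the reported mortality rates rounds to 52% and 46%
  expect_equal(round(100 * annual_mortality(0.73)), 52)
  expect_equal(round(100 * annual_mortality(0.62)), 46)
  expect_equal(annual_mortality(0), 0)
  expect_error(annual_mortality(Inf), "finite")
})

test_that("disturbance filter honors the boolean column", {
  catch <- data.frame(area = "heat", year = c(1996L, 1997L), net_id = 1L,
                      length_class_lower = 10, length_class_width = 2.5,
                      count = 5, disturbed = c(TRUE, FALSE))
  out <- filter_disturbed(catch)
  expect_equal(out$year, 1997L)
  expect_false("disturbed" %in% names(out))
})

test_that("1 cm classes rebin to 2.5 cm by width overlap", {
  catch <- data.frame(area = "ref", year = 2001L, net_id = 1L,
                      length_class_lower = c(10, 11, 12),
                      length_class_width = 1, count = c(10, 10, 10))
  out <- rebin_catch(catch)
  # [10,11) and [11,12) fall in [10,12.5); [12,13) splits 0.5/0.5
  expect_equal(out$length_class_lower, c(10, 12.5))
  expect_equal(out$count, c(25, 5))
  expect_equal(sum(out$count), sum(catch$count))
})
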