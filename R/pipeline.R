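# End-to-end pipeline: simulate -> back-calculate -> growth models ->
# mortality -> size spectrum -> mean size/age -> report.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the populations to simulate (or
#'   NULL when `fish`/`catch` tables are supplied to [run_pipeline()]).
#' @param sampler a [sampler_config()] shared by all model fits.
#' @param stages named logical vector enabling stages `vbge`, `growth`,
#'   `mortality`, `spectrum`, `mean_size_age`.
#' @param n_aged_per_area size of the aged subsample per area (the fish that
#'   get operculum readings and enter the growth models and age-length keys).
#' @param cohort_range optional `c(first, last)` filter on cohorts entering
#'   the growth models (the sensitivity filter).
#' @param exclude_disturbed drop catch records flagged as disturbed.
#' @param lw_a,lw_b length-weight parameters for the biomass spectrum.
#' @param seed master seed; fixes every downstream stage.
#' @param outdir optional directory for CSV/JSON outputs.
#' @return a list of class `tf_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            sampler = sampler_config(),
                            stages = c(vbge = TRUE, growth = TRUE,
                                       mortality = TRUE, spectrum = TRUE,
                                       mean_size_age = TRUE),
                            n_aged_per_area = 500L,
                            cohort_range = NULL,
                            exclude_disturbed = TRUE,
                            lw_a = 0.01, lw_b = 3,
                            seed = 1L, outdir = NULL) {
  stage_names <- c("vbge", "growth", "mortality", "spectrum", "mean_size_age")
  st <- stats::setNames(rep(TRUE, 5L), stage_names)
  st[names(stages)] <- stages
  structure(list(sim = sim, sampler = sampler, stages = st,
                 n_aged_per_area = as.integer(n_aged_per_area),
                 cohort_range = cohort_range,
                 exclude_disturbed = exclude_disturbed,
                 lw_a = lw_a, lw_b = lw_b,
                 seed = as.integer(seed), outdir = outdir),
            class = "tf_pipeline_config")
}

#' Reduced demo configuration
#'
#' A scaled-down stated-world run (fewer recruits, shorter chains) that
#' completes end-to-end in a few minutes on one CPU while preserving every
#' stage and the direction of all the headline contrasts.
#'
#' @param seed master seed.
#' @return a [pipeline_config()].
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    sim = sim_config(recruits_per_cohort = 400L, nets_per_year = 16L),
    sampler = sampler_config(chains = 3L, iter = 1500L),
    n_aged_per_area = 400L,
    seed = seed
  )
}

#' Run the full analysis pipeline
#'
#' Simulates the heated and reference populations (or consumes supplied
#' tables), then runs every enabled stage: the von Bertalanffy size-at-age
#' model, the allometric specific-growth model on back-calculated lengths,
#' age-length-key expansion plus catch-curve mortality, the MLEbin biomass
#' size spectrum, and the lognormal mean size/age models. Returns all stage
#' outputs plus a report of the headline derived quantities (percent
#' differences in growth parameters, mortality rates and annual mortality,
#' spectrum exponents, mean size and age differences).
#'
#' @param config a [pipeline_config()].
#' @param fish,catch optional pre-built tables replacing the simulation.
#' @return a list of class `tf_pipeline_result` with elements `fish`, `catch`,
#'   `aged`, per-stage fits, and `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), fish = NULL,
                         catch = NULL) {
  stopifnot(inherits(config, "tf_pipeline_config"))
  set.seed(config$seed)
  sim <- config$sim
  if (!is.null(sim)) sim$seed <- NULL  # master seed governs all stages
  if (is.null(fish)) fish <- simulate_cohorts(sim)
  if (is.null(catch)) catch <- simulate_catch(fish, sim)
  if (config$exclude_disturbed) catch <- filter_disturbed(catch)
  retained <- attr(catch, "retained_ids")
  pool <- if (!is.null(retained)) fish[fish$id %in% retained, ] else fish
  # length-stratified ageing subsample (as in the survey practice): take fish
  # evenly across 2.5 cm classes so the age-length key covers every catch class
  aged <- do.call(rbind, lapply(split(pool, pool$area), function(f)
    stratified_sample(f, config$n_aged_per_area)))
  rownames(aged) <- NULL
  if (!is.null(config$cohort_range))
    aged <- aged[aged$cohort >= config$cohort_range[1] &
                   aged$cohort <= config$cohort_range[2], ]
  res <- list(config = config, fish = fish, catch = catch, aged = aged)
  report <- list(seed = config$seed)

  if (config$stages[["vbge"]]) {
    res$vbge <- fit_vbge(aged, config = config$sampler)
    pd_L <- percent_difference(posterior_draws(res$vbge, "mu_Linf[heat]"),
                               posterior_draws(res$vbge, "mu_Linf[ref]"))
    pd_K <- percent_difference(posterior_draws(res$vbge, "mu_K[heat]"),
                               posterior_draws(res$vbge, "mu_K[ref]"))
    report$Linf_percent_diff <- pd_L$median
    report$K_percent_diff <- pd_K$median
    ages <- seq(min(aged$age), max(aged$age))
    ph <- predict_size_at_age(res$vbge, ages, "heat")
    pr <- predict_size_at_age(res$vbge, ages, "ref")
    report$size_at_age_ratio <- stats::setNames(ph$median / pr$median,
                                                paste0("age", ages))
    report$vbge_converged <- check_convergence(res$vbge)$pass
  }
  if (config$stages[["growth"]]) {
    obs <- growth_observations(aged, s = sim$s)
    res$growth_obs <- obs
    res$growth <- fit_allometric_growth(obs, config = config$sampler)
    da <- posterior_draws(res$growth, "mu_alpha[heat]") -
      posterior_draws(res$growth, "mu_alpha[ref]")
    report$alpha_percent_diff <- percent_difference(
      posterior_draws(res$growth, "mu_alpha[heat]"),
      posterior_draws(res$growth, "mu_alpha[ref]"))$median
    report$alpha_prob_below_zero <- prob_below_zero(da)
    report$growth_converged <- check_convergence(res$growth)$pass
  }
  if (config$stages[["mortality"]]) {
    caa <- list()
    for (a in c("heat", "ref")) {
      alk <- build_alk(aged, area = a)
      caa[[a]] <- expand_catch(rebin_catch(catch), alk)
    }
    caa <- do.call(rbind, caa)
    res$catch_at_age <- caa
    limb <- select_descending_limb(caa)
    res$catch_curve <- fit_catch_curve(limb, interaction = TRUE,
                                       cohort_effects = "intercept",
                                       group = "year",
                                       config = config$sampler)
    Z <- mortality_Z(res$catch_curve)
    report$Z_heat <- stats::median(Z$Z_heat)
    report$Z_ref <- stats::median(Z$Z_ref)
    report$annual_mortality_heat <- annual_mortality(report$Z_heat)
    report$annual_mortality_ref <- annual_mortality(report$Z_ref)
    report$Z_diff_prob_below_zero <- prob_below_zero(Z$diff)
    report$mortality_converged <- check_convergence(res$catch_curve)$pass
  }
  if (config$stages[["spectrum"]]) {
    res$spectrum <- lapply(c(heat = "heat", ref = "ref"), function(a) {
      bins <- catch_to_mass_bins(catch, a, config$lw_a, config$lw_b)
      mlebin_fit(bins$counts, bins$edges)
    })
    report$gamma_heat <- res$spectrum$heat$b
    report$gamma_ref <- res$spectrum$ref$b
  }
  if (config$stages[["mean_size_age"]]) {
    size_dat <- catch_responses(catch = rebin_catch(catch),
                                response = "length")
    res$mean_size <- fit_lognormal(size_dat, config = config$sampler)
    ds <- posterior_mean_difference(res$mean_size)
    report$mean_size_diff_cm <- ds$median
    if (!is.null(res$catch_at_age)) {
      age_dat <- catch_responses(catch_at_age = res$catch_at_age,
                                 response = "age")
      res$mean_age <- fit_lognormal(age_dat, config = config$sampler)
      da <- posterior_mean_difference(res$mean_age)
      report$mean_age_diff_yr <- da$median
    }
  }
  res$report <- report
  class(res) <- "tf_pipeline_result"
  if (!is.null(config$outdir)) write_pipeline_outputs(res, config$outdir)
  res
}

#' @export
print.tf_pipeline_result <- function(x, ...) {
  r <- x$report
  cat("thermofish pipeline report (seed ", r$seed, ")\n", sep = "")
  fmt <- function(lab, v, unit = "") {
    if (!is.null(v)) cat(sprintf("  %-34s %s%s\n", lab,
                                 paste(round(v, 3), collapse = " "), unit))
  }
  fmt("Linf percent difference (heat-ref):", r$Linf_percent_diff, " %")
  fmt("K percent difference (heat-ref):", r$K_percent_diff, " %")
  fmt("alpha percent difference:", r$alpha_percent_diff, " %")
  fmt("P(alpha_heat - alpha_ref < 0):", r$alpha_prob_below_zero)
  fmt("Z heated / reference:", c(r$Z_heat, r$Z_ref), " 1/yr")
  fmt("annual mortality heated/reference:",
      c(r$annual_mortality_heat, r$annual_mortality_ref))
  fmt("size-spectrum gamma heated/ref:", c(r$gamma_heat, r$gamma_ref))
  fmt("mean size difference (heat-ref):", r$mean_size_diff_cm, " cm")
  fmt("mean age difference (heat-ref):", r$mean_age_diff_yr, " yr")
  invisible(x)
}

# Length-stratified subsample: allocate n slots round-robin across 2.5 cm
# length classes (each nonempty class keeps at least one fish when n allows).
stratified_sample <- function(fish, n, width = 2.5) {
  n <- min(n, nrow(fish))
  cls <- floor(fish$length_at_catch / width) * width
  groups <- split(seq_len(nrow(fish)), cls)
  groups <- lapply(groups, function(g) g[sample.int(length(g))])
  take <- integer(0)
  k <- 1L
  while (length(take) < n) {
    picks <- vapply(groups, function(g) if (length(g) >= k) g[k] else NA_integer_,
                    0L)
    picks <- picks[!is.na(picks)]
    if (length(picks) == 0L) break
    take <- c(take, picks[seq_len(min(length(picks), n - length(take)))])
    k <- k + 1L
  }
  fish[sort(take), , drop = FALSE]
}

#' Validate analysis input tables
#'
#' Report-only checks of the record invariants: positive lengths and counts,
#' `cohort + age = catch_year`, radii strictly increasing with one radius per
#' annulus, class lowers aligned to the class-width grid, and an advisory when
#' 1 cm and 2.5 cm class years are mixed.
#'
#' @param fish optional fish table ([simulate_cohorts()] layout).
#' @param catch optional catch table ([simulate_catch()] layout).
#' @return data.frame of violations (`table`, `row`, `check`, `message`);
#'   zero rows when clean. Advisories carry `check = "advisory"`.
#' @export
validate_inputs <- function(fish = NULL, catch = NULL) {
  v <- list()
  flag <- function(table, row, check, msg)
    v[[length(v) + 1L]] <<- data.frame(table = table, row = row,
                                       check = check, message = msg)
  if (!is.null(fish)) {
    bad <- which(fish$catch_year - fish$age != fish$cohort)
    for (i in bad) flag("fish", i, "cohort", "catch_year - age != cohort")
    bad <- which(fish$length_at_catch <= 0)
    for (i in bad) flag("fish", i, "length", "non-positive length at catch")
    if (!is.null(fish$radii)) {
      for (i in seq_len(nrow(fish))) {
        r <- fish$radii[[i]]
        if (length(r) != fish$age[i])
          flag("fish", i, "radii", "number of radii differs from age")
        if (length(r) > 1 && any(diff(r) <= 0))
          flag("fish", i, "radii", "radii not strictly increasing")
      }
    }
  }
  if (!is.null(catch)) {
    bad <- which(catch$count < 0)
    for (i in bad) flag("catch", i, "count", "negative count")
    bad <- which(!catch$length_class_width %in% c(1, 2.5))
    for (i in bad) flag("catch", i, "width", "class width not 1 or 2.5 cm")
    off <- abs(catch$length_class_lower / catch$length_class_width -
                 round(catch$length_class_lower / catch$length_class_width))
    for (i in which(off > 1e-9))
      flag("catch", i, "grid", "class lower not aligned to the width grid")
    if (length(unique(catch$length_class_width)) > 1L)
      flag("catch", NA_integer_, "advisory",
           "mixed 1 cm and 2.5 cm class years; rebin with rebin_catch()")
  }
  if (length(v) == 0L)
    return(data.frame(table = character(), row = integer(),
                      check = character(), message = character()))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
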