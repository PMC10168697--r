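#' von Bertalanffy growth curve
#'
#' `L(t) = Linf * (1 - exp(-K * (t - t0)))`, the standard asymptotic growth
#' model: `Linf` is asymptotic length (cm), `K` the Brody growth coefficient
#' (1/yr) and `t0` the theoretical age at zero length (yr).
#'
#' @param age age in years.
#' @param Linf,K,t0 growth parameters.
#' @return length in cm (vectorized over any argument).
#' @export
vbge_length <- function(age, Linf, K, t0) {
  Linf * (1 - exp(-K * (age - t0)))
}

#' Simulation configuration
#'
#' The generative counterpart of the fitted models: two reproductively
#' isolated populations (a heated and a reference area) with cohort-varying
#' von Bertalanffy parameters drawn from area-level hyper-distributions,
#' area-specific exponential survival, Student-t observation noise on log
#' length, operculum annulus radii consistent with the back-calculation power
#' law `L = kappa * R^s`, dome-shaped (lognormal in length) gillnet
#' selectivity, and catch recorded per net-night in 2.5 cm length classes
#' (1 cm classes in the configured late years).
#'
#' Defaults are the stated study system: hyper-means at the heated/reference
#' posterior medians (`Linf` 45.7/39.4 cm, `K` 0.19/0.15 1/yr, `t0` -0.5 yr),
#' mortality `Z` 0.73/0.62 1/yr, allometric growth `alpha` 512/433 and
#' `theta` -1.13/-1.18, back-calculation exponent `s = 0.861`, cohorts
#' 1981-1997 and catch years 1987-2003 with 1 cm classes in 2001-2003.
#'
#' @param mu_Linf,mu_K,t0 named (`heat`, `ref`) area hyper-means.
#' @param sigma_Linf,sigma_K between-cohort SDs of the growth parameters.
#' @param Z instantaneous mortality (1/yr) per area.
#' @param alpha,theta allometric specific-growth parameters per area
#'   (`G = alpha * L^theta`, `G` in %/yr).
#' @param sigma_alpha_cohort,sigma_alpha_id,sigma_G,nu_G nested variation and
#'   residual noise of the specific-growth generator.
#' @param nu,sigma_obs Student-t df and scale of observation noise on log
#'   length at catch.
#' @param kappa,s back-calculation constants (`L = kappa * R^s`).
#' @param radii_jitter multiplicative lognormal jitter SD on the annulus
#'   radii (0 keeps the back-calculation round trip exact).
#' @param sel_mode,sel_spread mode (cm) and lognormal spread of the
#'   dome-shaped gillnet selectivity.
#' @param cohorts,catch_years,years_1cm year ranges.
#' @param nets_per_year net deployments (net-nights) per area and year.
#' @param recruits_per_cohort recruits entering each cohort per area.
#' @param max_age oldest age retained.
#' @param seed optional seed fixing all randomness of the generators.
#' @return a list of class `tf_sim_config`.
#' @export
sim_config <- function(mu_Linf = c(heat = 45.7, ref = 39.4),
                       mu_K = c(heat = 0.19, ref = 0.15),
                       t0 = c(heat = -0.5, ref = -0.5),
                       sigma_Linf = c(heat = 3, ref = 3),
                       sigma_K = c(heat = 0.02, ref = 0.02),
                       Z = c(heat = 0.73, ref = 0.62),
                       alpha = c(heat = 512, ref = 433),
                       theta = c(heat = -1.13, ref = -1.18),
                       sigma_alpha_cohort = 25, sigma_alpha_id = 50,
                       sigma_G = 10, nu_G = 10,
                       nu = 10, sigma_obs = 0.05,
                       kappa = 8, s = 0.861, radii_jitter = 0,
                       sel_mode = 20, sel_spread = 0.4,
                       cohorts = 1981:1997, catch_years = 1987:2003,
                       years_1cm = 2001:2003,
                       nets_per_year = 16, recruits_per_cohort = 200,
                       max_age = 25, seed = NULL) {
  cfg <- list(mu_Linf = mu_Linf, mu_K = mu_K, t0 = t0,
              sigma_Linf = sigma_Linf, sigma_K = sigma_K, Z = Z,
              alpha = alpha, theta = theta,
              sigma_alpha_cohort = sigma_alpha_cohort,
              sigma_alpha_id = sigma_alpha_id, sigma_G = sigma_G,
              nu_G = nu_G, nu = nu, sigma_obs = sigma_obs,
              kappa = kappa, s = s, radii_jitter = radii_jitter,
              sel_mode = sel_mode, sel_spread = sel_spread,
              cohorts = cohorts, catch_years = catch_years,
              years_1cm = years_1cm, nets_per_year = nets_per_year,
              recruits_per_cohort = recruits_per_cohort,
              max_age = max_age, seed = seed)
  for (p in c("mu_Linf", "mu_K", "Z", "kappa", "s"))
    if (any(cfg[[p]] <= 0)) stop("'", p, "' must be positive")
  if (any(c(sigma_Linf, sigma_K, sigma_obs, radii_jitter) < 0))
    stop("scale parameters must be non-negative")
  if (length(cohorts) < 1L || length(catch_years) < 1L)
    stop("cohort and catch-year ranges must be nonempty")
  structure(cfg, class = "tf_sim_config")
}

area_par <- function(x, area) {
  if (length(x) == 1L) return(unname(x))
  unname(x[[area]])
}

#' Simulate aged individuals from the heated and reference populations
#'
#' For each area and cohort, cohort-level `Linf` and `K` are drawn from
#' independent normals around the area hyper-means (no cross-parameter
#' correlation). Each recruit gets an integer age at death from exponential
#' survival at rate `Z` (deaths fall between birthdays, so annual survival is
#' `exp(-Z)`), is retained if its catch year (`cohort + age`) falls inside the
#' catch window, gets true lengths-at-age from the growth curve, an observed
#' length-at-catch with Student-t noise on the log scale, and annulus radii by
#' exact inversion of the back-calculation power law
#' (`r_a = R * (L_a / L_s)^(1/s)`), optionally jittered.
#'
#' @param config a [sim_config()].
#' @param keep_all retain fish whose catch year falls outside the catch
#'   window (useful for survival checks); default FALSE.
#' @return a data.frame with one row per fish: `id`, `area`, `cohort`,
#'   `catch_year`, `age`, `length_at_catch` and a list-column `radii`
#'   (strictly increasing, last element = operculum radius at catch).
#' @export
simulate_cohorts <- function(config, keep_all = FALSE) {
  stopifnot(inherits(config, "tf_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  feasible <- any(outer(config$cohorts, config$catch_years,
                        function(c, y) y - c >= 1 & y - c <= config$max_age))
  if (!feasible)
    stop("cohort window incompatible with catch-year window: no cohort can ",
         "be caught at a positive age")
  rows <- list()
  id0 <- 0L
  for (area in c("heat", "ref")) {
    Zq <- 1 - exp(-area_par(config$Z, area))
    for (cohort in config$cohorts) {
      Linf_j <- -1; K_j <- -1
      while (Linf_j <= 0)
        Linf_j <- stats::rnorm(1, area_par(config$mu_Linf, area),
                               area_par(config$sigma_Linf, area))
      while (K_j <= 0)
        K_j <- stats::rnorm(1, area_par(config$mu_K, area),
                            area_par(config$sigma_K, area))
      t0_a <- area_par(config$t0, area)
      n <- config$recruits_per_cohort
      age <- pmin(1L + stats::rgeom(n, Zq), config$max_age)
      catch_year <- cohort + age
      keep <- if (keep_all) rep(TRUE, n) else catch_year %in% config$catch_years
      if (!any(keep)) next
      age <- age[keep]; catch_year <- catch_year[keep]
      m <- length(age)
      noise <- if (config$sigma_obs > 0)
        config$sigma_obs * stats::rt(m, config$nu) else numeric(m)
      L_true_catch <- vbge_length(age, Linf_j, K_j, t0_a)
      L_obs <- exp(log(L_true_catch) + noise)
      radii <- vector("list", m)
      for (k in seq_len(m)) {
        La <- vbge_length(seq_len(age[k]), Linf_j, K_j, t0_a)
        r <- (La / config$kappa)^(1 / config$s)
        if (config$radii_jitter > 0 && age[k] > 1L) {
          jit <- exp(stats::rnorm(age[k] - 1L, 0, config$radii_jitter))
          r[-age[k]] <- r[-age[k]] * jit
          r <- cummax(r * (1 + 1e-9 * seq_along(r)))  # keep strictly increasing
          r[age[k]] <- max(r)
        }
        radii[[k]] <- r
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = id0 + seq_len(m), area = area, cohort = cohort,
        catch_year = catch_year, age = age, length_at_catch = L_obs
      )
      rows[[length(rows)]]$radii <- I(radii)
      id0 <- id0 + m
    }
  }
  if (length(rows) == 0L)
    stop("no fish retained; check the cohort and catch-year windows")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dome-shaped gillnet selectivity
#'
#' Lognormal-in-length retention curve with maximum 1 at `mode`.
#'
#' @param length fish length (cm).
#' @param mode modal length (cm) of the dome.
#' @param spread lognormal spread (SD of log length).
#' @return retention probability in (0, 1].
#' @export
gillnet_selectivity <- function(length, mode, spread) {
  exp(-(log(length / mode))^2 / (2 * spread^2))
}

#' Simulate binned catch records from a set of fish
#'
#' Each fish is retained with dome-shaped selectivity probability, allocated
#' uniformly to one of the area-year's net deployments, and binned to the
#' length-class grid of its catch year (2.5 cm, or 1 cm in the configured late
#' years). Counts sum to the number of retained fish.
#'
#' @param fish data.frame from [simulate_cohorts()].
#' @param config a [sim_config()].
#' @param selectivity logical; FALSE retains every fish (useful for
#'   conservation checks).
#' @return data.frame of catch records: `area`, `year`, `net_id`,
#'   `length_class_lower`, `length_class_width`, `count`.
#' @export
simulate_catch <- function(fish, config, selectivity = TRUE) {
  stopifnot(inherits(config, "tf_sim_config"), nrow(fish) > 0)
  p <- if (selectivity)
    gillnet_selectivity(fish$length_at_catch, config$sel_mode, config$sel_spread)
  else rep(1, nrow(fish))
  keep <- stats::runif(nrow(fish)) < p
  f <- fish[keep, , drop = FALSE]
  if (nrow(f) == 0L)
    return(data.frame(area = character(), year = integer(), net_id = integer(),
                      length_class_lower = numeric(),
                      length_class_width = numeric(), count = integer()))
  width <- ifelse(f$catch_year %in% config$years_1cm, 1.0, 2.5)
  lower <- floor(f$length_at_catch / width) * width
  net <- sample.int(config$nets_per_year, nrow(f), replace = TRUE)
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(f))),
    by = list(area = f$area, year = f$catch_year, net_id = net,
              length_class_lower = lower, length_class_width = width),
    FUN = sum
  )
  agg <- agg[order(agg$area, agg$year, agg$net_id, agg$length_class_lower), ]
  rownames(agg) <- NULL
  attr(agg, "retained_ids") <- f$id
  agg
}

#' Simulate specific-growth observations from the allometric model
#'
#' Draws growth observations directly from `G = alpha * L^theta` with nested
#' individual-within-cohort variation on `alpha` and Student-t residual noise,
#' the generative counterpart of the allometric growth model. Lengths along
#' each individual's trajectory come from the area growth curve.
#'
#' @param config a [sim_config()].
#' @param n_id_per_area individuals per area.
#' @return data.frame with `id`, `area`, `cohort`, `age_start`, `L_geo`, `G`.
#' @export
simulate_growth_data <- function(config, n_id_per_area = 300L) {
  stopifnot(inherits(config, "tf_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rows <- list()
  id0 <- 0L
  for (area in c("heat", "ref")) {
    a_mu <- area_par(config$alpha, area)
    th <- area_par(config$theta, area)
    coh <- sample(config$cohorts, n_id_per_area, replace = TRUE)
    a_coh <- stats::rnorm(length(config$cohorts), 0, config$sigma_alpha_cohort)
    names(a_coh) <- as.character(config$cohorts)
    for (k in seq_len(n_id_per_area)) {
      # ages at catch of the aged subsample: length-stratified ageing gives a
      # much flatter age distribution than raw survival (~5 increments/fish)
      age <- sample(2:10, 1L)
      # individually varying growth trajectories (back-calculated lengths
      # differ between fish, as in real increment data)
      Linf_k <- -1; K_k <- -1
      while (Linf_k <= 0)
        Linf_k <- stats::rnorm(1, area_par(config$mu_Linf, area),
                               area_par(config$sigma_Linf, area) + 1)
      while (K_k <= 0)
        K_k <- stats::rnorm(1, area_par(config$mu_K, area),
                            area_par(config$sigma_K, area) + 0.01)
      La <- vbge_length(seq_len(age), Linf_k, K_k, area_par(config$t0, area))
      Lg <- sqrt(La[-1] * La[-age])
      alpha_k <- a_mu + a_coh[[as.character(coh[k])]] +
        stats::rnorm(1, 0, config$sigma_alpha_id)
      G <- alpha_k * Lg^th + config$sigma_G * stats::rt(age - 1L, config$nu_G)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id0 + k, area = area, cohort = coh[k],
        age_start = seq_len(age - 1L), L_geo = Lg, G = G
      )
    }
    id0 <- id0 + n_id_per_area
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate catch-at-age CPUE with exponential decline
#'
#' Direct generator for catch-curve recovery checks: CPUE declines
#' exponentially with age at the area's mortality rate, with a shared random
#' year effect and lognormal observation noise.
#'
#' @param config a [sim_config()].
#' @param years number of survey years.
#' @param ages integer ages observed (the descending limb).
#' @param q catchability scaling (CPUE of a hypothetical age-0 class).
#' @param sd_log lognormal observation noise SD.
#' @param sd_year SD of the year-level random intercept (log scale).
#' @return data.frame `area`, `year`, `age`, `cohort`, `cpue`.
#' @export
simulate_catch_at_age <- function(config, years = 15L, ages = 2:8,
                                  q = 1000, sd_log = 0.3, sd_year = 0.2) {
  stopifnot(inherits(config, "tf_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  yr <- config$catch_years[seq_len(min(years, length(config$catch_years)))]
  rows <- list()
  for (area in c("heat", "ref")) {
    Z <- area_par(config$Z, area)
    u <- stats::rnorm(length(yr), 0, sd_year)
    for (j in seq_along(yr)) {
      cpue <- q * exp(-Z * ages + u[j] +
                        stats::rnorm(length(ages), 0, sd_log))
      rows[[length(rows) + 1L]] <- data.frame(
        area = area, year = yr[j], age = as.integer(ages),
        cohort = yr[j] - as.integer(ages), cpue = cpue
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
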