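# Hierarchical Bayesian growth models.
#
# Both models use robust Student-t likelihoods and cohort-varying parameters
# drawn from area hyper-distributions (non-centered in the sampler). The VBGE
# model is fitted to age and length at catch only; the allometric model to
# back-calculated specific growth rates.

area_code <- function(area) {
  a <- match(area, c("heat", "ref")) - 1L
  if (anyNA(a)) stop("'area' must be 'heat' or 'ref'")
  a
}

par_names <- function(base, n, labels = c("heat", "ref")) {
  if (n == 1L) base else paste0(base, "[", labels[seq_len(n)], "]")
}

#' Fit the hierarchical von Bertalanffy growth model
#'
#' Fits length-at-age on the log scale with a Student-t likelihood:
#' `log(L_i) ~ t(nu, log(Linf_j (1 - exp(-K_j (t - t0)))), sigma)`, where
#' `Linf` and `K` vary by cohort around area hyper-means (independent normals,
#' no cross-parameter correlation) and `t0` is a per-area fixed effect. Any of
#' `Linf`, `K`, `t0` can be shared between areas or area-specific, giving the
#' 8 model variants. `Linf` and `K` hyper-means are sampled on the log scale
#' (with their stated natural-scale priors applied through a change of
#' variables) and proposals implying a non-positive mean length are rejected.
#'
#' Priors: `mu_Linf ~ N(45, 20)`, `mu_K ~ N(0.2, 0.1)`, `t0 ~ N(-0.5, 1)`,
#' `nu ~ Gamma(2, 0.1)`, all scale parameters half-Student-t(3, 0, 2.5).
#'
#' @param records data.frame with `age`, `length_at_catch`, `area`
#'   (`"heat"`/`"ref"`), `cohort`.
#' @param area_specific named logical vector: which of `Linf`, `K`, `t0` get
#'   area-specific parameters.
#' @param config a [sampler_config()].
#' @param seed optional seed.
#' @return a `tf_fit`; convergence should be checked with
#'   [check_convergence()] (a fit with any split-R-hat >= 1.1 did not
#'   converge and is flagged, not an error).
#' @export
fit_vbge <- function(records,
                     area_specific = c(Linf = TRUE, K = TRUE, t0 = TRUE),
                     config = sampler_config(), seed = NULL) {
  stopifnot(all(c("age", "length_at_catch", "area", "cohort") %in% names(records)),
            all(records$length_at_catch > 0), all(records$age > 0))
  for (a in c("heat", "ref")) {
    nc <- length(unique(records$cohort[records$area == a]))
    if (nc < 2L)
      stop("need >= 2 cohorts per area for the hierarchical variances (", a,
           " has ", nc, ")")
  }
  cohorts <- sort(unique(records$cohort))
  ncoh <- length(cohorts)
  data <- list(
    y = log(records$length_at_catch),
    t = as.numeric(records$age),
    area = area_code(records$area),
    coh = match(records$cohort, cohorts) - 1L,
    ncoh = ncoh,
    area_Linf = isTRUE(area_specific[["Linf"]]),
    area_K = isTRUE(area_specific[["K"]]),
    area_t0 = isTRUE(area_specific[["t0"]])
  )
  nL <- if (data$area_Linf) 2L else 1L
  nK <- if (data$area_K) 2L else 1L
  nT <- if (data$area_t0) 2L else 1L
  zL_names <- if (nL == 2L)
    paste0("z_Linf[", rep(c("heat", "ref"), each = ncoh), ",", cohorts, "]")
  else paste0("z_Linf[", cohorts, "]")
  zK_names <- if (nK == 2L)
    paste0("z_K[", rep(c("heat", "ref"), each = ncoh), ",", cohorts, "]")
  else paste0("z_K[", cohorts, "]")
  pars <- c(par_names("mu_Linf", nL), par_names("mu_K", nK),
            par_names("t0", nT), par_names("sigma_Linf", nL),
            par_names("sigma_K", nK), "nu", "sigma", zL_names, zK_names)
  transform <- c(rep("exp", nL), rep("exp", nK), rep("identity", nT),
                 rep("exp", nL), rep("exp", nK), "exp", "exp",
                 rep("identity", nL * ncoh + nK * ncoh))
  init <- c(rep(log(40), nL), rep(log(0.18), nK), rep(-0.5, nT),
            rep(log(2), nL), rep(log(0.03), nK), log(10), log(0.1),
            rep(0, nL * ncoh + nK * ncoh))
  scale0 <- c(rep(0.03, nL), rep(0.05, nK), rep(0.05, nT),
              rep(0.2, nL), rep(0.2, nK), 0.3, 0.05,
              rep(0.3, nL * ncoh + nK * ncoh))
  # 0-based parameter indices for the reparameterization moves
  iL <- 0L; iK <- iL + nL; iT <- iK + nK; isL <- iT + nT; isK <- isL + nL
  izL <- isK + nK + 2L; izK <- izL + nL * ncoh
  fam <- list()
  sfam <- list()
  for (a in seq_len(nL) - 1L) {
    zidx <- izL + a * ncoh + seq_len(ncoh) - 1L
    fam[[length(fam) + 1L]] <- list(h = iL + a, hlog = TRUE, s = isL + a, z = zidx)
    sfam[[length(sfam) + 1L]] <- list(s = isL + a, z = zidx)
  }
  for (a in seq_len(nK) - 1L) {
    zidx <- izK + a * ncoh + seq_len(ncoh) - 1L
    fam[[length(fam) + 1L]] <- list(h = iK + a, hlog = TRUE, s = isK + a, z = zidx)
    sfam[[length(sfam) + 1L]] <- list(s = isK + a, z = zidx)
  }
  # per-cohort (z_Linf, z_K) pairs trade off along the growth-curve ridge;
  # update them jointly, as well as each area's hyper-parameter set
  blocks <- list()
  for (a in 0:1) {
    ab <- unique(c(iL + min(a, nL - 1L), iK + min(a, nK - 1L),
                   iT + min(a, nT - 1L), isL + min(a, nL - 1L),
                   isK + min(a, nK - 1L)))
    # repeat the area-hyper block: the (Linf, K, t0) ridge is the mixing
    # bottleneck and extra joint updates are cheap
    for (rep in 1:5) blocks[[length(blocks) + 1L]] <- ab
  }
  for (a in seq_len(nK) - 1L) {
    for (j in seq_len(ncoh) - 1L) {
      blocks[[length(blocks) + 1L]] <-
        c(izL + min(a, nL - 1L) * ncoh + j, izK + a * ncoh + j)
    }
  }
  fit <- run_mcmc("vbge", data, init, scale0, pars, transform, config,
                  spec = list(model = "vbge", area_specific = area_specific,
                              cohorts = cohorts,
                              age_range = range(records$age)),
                  seed = seed, blocks = blocks,
                  shift_fam = fam, scale_fam = sfam)
  fit
}

#' The 8 von Bertalanffy variant definitions
#'
#' All combinations of shared vs. area-specific `Linf`, `K`, `t0`.
#'
#' @return a list of named logical vectors usable as `area_specific` in
#'   [fit_vbge()].
#' @export
vbge_variants <- function() {
  grid <- expand.grid(Linf = c(TRUE, FALSE), K = c(TRUE, FALSE),
                      t0 = c(TRUE, FALSE))
  lapply(seq_len(nrow(grid)), function(i)
    c(Linf = grid$Linf[i], K = grid$K[i], t0 = grid$t0[i]))
}

#' Fit the hierarchical allometric specific-growth model
#'
#' Fits `G_i ~ t(nu, alpha_{j,k} * L^theta, sigma)` where specific growth `G`
#' (%/yr) declines with geometric mean length `L` and the initial growth
#' `alpha` varies across individuals `k` nested within cohorts `j` (normal
#' deviations at both levels). `alpha` is always area-specific; `theta` can be
#' shared or area-specific (the two compared variants).
#'
#' Priors: `mu_alpha ~ N(500, 100)`, `theta ~ N(-1.2, 0.3)`,
#' `nu ~ Gamma(2, 0.1)`, all scale parameters half-Student-t(3, 0, 13.3).
#'
#' @param observations data.frame from [growth_observations()] or
#'   [simulate_growth_data()]: columns `id`, `area`, `cohort`, `L_geo`, `G`.
#' @param area_specific_theta if FALSE, one `theta` shared by both areas.
#' @param config a [sampler_config()].
#' @param seed optional seed.
#' @return a `tf_fit`.
#' @export
fit_allometric_growth <- function(observations, area_specific_theta = TRUE,
                                  config = sampler_config(), seed = NULL) {
  stopifnot(all(c("id", "area", "cohort", "L_geo", "G") %in% names(observations)),
            all(observations$L_geo > 0))
  gc_lab <- sort(unique(paste0(observations$area, ",", observations$cohort)))
  gi_lab <- sort(unique(observations$id))
  data <- list(
    y = observations$G,
    lL = log(observations$L_geo),
    area = area_code(observations$area),
    gcoh = match(paste0(observations$area, ",", observations$cohort), gc_lab) - 1L,
    gid = match(observations$id, gi_lab) - 1L,
    Gc = length(gc_lab), Gi = length(gi_lab),
    area_theta = isTRUE(area_specific_theta)
  )
  nT <- if (data$area_theta) 2L else 1L
  pars <- c("mu_alpha[heat]", "mu_alpha[ref]", par_names("theta", nT),
            "sigma_cohort", "sigma_id", "nu", "sigma",
            paste0("z_cohort[", gc_lab, "]"), paste0("z_id[", gi_lab, "]"))
  transform <- c("identity", "identity", rep("identity", nT),
                 "exp", "exp", "exp", "exp",
                 rep("identity", data$Gc + data$Gi))
  init <- c(480, 480, rep(-1.2, nT), log(20), log(40), log(10), log(10),
            rep(0, data$Gc + data$Gi))
  scale0 <- c(10, 10, rep(0.01, nT), 0.2, 0.1, 0.3, 0.05,
              rep(0.3, data$Gc + data$Gi))
  # 0-based indices for the reparameterization moves
  isC <- 2L + nT; isI <- isC + 1L
  izC <- isI + 3L; izI <- izC + data$Gc
  gc_area <- sub(",.*$", "", gc_lab)
  fam <- list()
  for (a in 0:1) {
    zidx <- izC + which(gc_area == c("heat", "ref")[a + 1L]) - 1L
    fam[[length(fam) + 1L]] <- list(h = a, hlog = FALSE, s = isC, z = zidx)
  }
  sfam <- list(list(s = isC, z = izC + seq_len(data$Gc) - 1L),
               list(s = isI, z = izI + seq_len(data$Gi) - 1L))
  run_mcmc("allo", data, init, scale0, pars, transform, config,
           spec = list(model = "allo", area_specific_theta = area_specific_theta,
                       cohorts = gc_lab),
           seed = seed, shift_fam = fam, scale_fam = sfam)
}

#' Percent difference between two posterior draw vectors
#'
#' Summarizes `100 * (a - b) / b`, the percent contrast used for the
#' heated-vs-reference parameter comparisons.
#'
#' @param draws_a,draws_b equal-length draw vectors (scalars allowed).
#' @return list with `median`, `l95`, `u95`, and the `draws` of the percent
#'   difference.
#' @export
percent_difference <- function(draws_a, draws_b) {
  if (length(draws_a) != length(draws_b))
    stop("draw vectors must have equal length")
  if (any(draws_b == 0)) {
    warning("dropping ", sum(draws_b == 0), " division-by-zero draw(s)")
    keep <- draws_b != 0
    draws_a <- draws_a[keep]; draws_b <- draws_b[keep]
  }
  if (length(draws_a) == 0L) stop("no valid draws")
  d <- 100 * (draws_a - draws_b) / draws_b
  q <- stats::quantile(d, c(0.5, 0.025, 0.975), names = FALSE)
  list(median = q[1], l95 = q[2], u95 = q[3], draws = d)
}

#' Posterior probability mass below zero
#'
#' Monte-Carlo fraction of draws below zero, used to express the strength of
#' a directional contrast (e.g. the mass of `alpha_heat - alpha_ref` below 0).
#'
#' @param draws_diff nonempty numeric vector of draws.
#' @return fraction in `[0, 1]`.
#' @export
prob_below_zero <- function(draws_diff) {
  if (length(draws_diff) == 0L) stop("'draws_diff' is empty")
  mean(draws_diff < 0)
}

#' Posterior predictive size-at-age (global mean curve)
#'
#' Summaries of the global posterior predictive mean (group-level cohort
#' effects excluded) of the fitted VBGE model, exponentiated back to the cm
#' scale: for each draw, `Linf (1 - exp(-K (t - t0)))` at the area's
#' hyper-parameters.
#'
#' @param fit a `tf_fit` from [fit_vbge()].
#' @param ages ages (years) at which to predict.
#' @param area `"heat"` or `"ref"`.
#' @return data.frame with `age`, `median`, 50% and 90% interval bounds, and
#'   `extrapolated` flagging ages outside the fitted age range.
#' @export
predict_size_at_age <- function(fit, ages, area = c("heat", "ref")) {
  stopifnot(inherits(fit, "tf_fit"), fit$spec$model == "vbge")
  area <- match.arg(area)
  pick <- function(base) {
    nm <- paste0(base, "[", area, "]")
    if (!nm %in% fit$pars) nm <- base
    posterior_draws(fit, nm)
  }
  Linf <- pick("mu_Linf"); K <- pick("mu_K"); t0 <- pick("t0")
  rng <- fit$spec$age_range
  extrap <- ages < rng[1] | ages > rng[2]
  if (any(extrap))
    warning("prediction extrapolates beyond the fitted age range [",
            rng[1], ", ", rng[2], "]")
  out <- lapply(ages, function(a) {
    L <- vbge_length(a, Linf, K, t0)
    L <- L[L > 0]
    q <- stats::quantile(L, c(0.5, 0.25, 0.75, 0.05, 0.95), names = FALSE)
    data.frame(age = a, median = q[1], l50 = q[2], u50 = q[3],
               l90 = q[4], u90 = q[5])
  })
  out <- do.call(rbind, out)
  out$extrapolated <- extrap
  out
}

#' Prior predictive draws from the VBGE model
#'
#' Draws parameters from the VBGE priors (respecting the model's positivity
#' constraints on `Linf`, `K` and the mean length) and simulates observed
#' lengths at the given ages, for prior predictive checking that the priors
#' give plausible, positive and finite lengths.
#'
#' @param n_draws number of prior parameter draws.
#' @param ages ages at which lengths are simulated.
#' @return matrix (`n_draws` x `length(ages)`) of simulated lengths (cm).
#' @export
prior_predictive_vbge <- function(n_draws = 1000L, ages = 1:10) {
  out <- matrix(NA_real_, n_draws, length(ages))
  for (i in seq_len(n_draws)) {
    repeat {
      Linf <- stats::rnorm(1, 45, 20)
      K <- stats::rnorm(1, 0.2, 0.1)
      t0 <- stats::rnorm(1, -0.5, 1)
      if (Linf > 0 && K > 0 && all(ages > t0)) break
    }
    sigma <- abs(2.5 * stats::rt(1, 3))
    nu <- stats::rgamma(1, 2, rate = 0.1)
    mu <- log(vbge_length(ages, Linf, K, t0))
    out[i, ] <- exp(mu + sigma * stats::rt(length(ages), nu))
  }
  out
}
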