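# Posterior predictive machinery. The per-observation means are reconstructed
# in R, independently of the C++ likelihood code, from the stored data and a
# raw draw; this doubles as a cross-check oracle of the compiled likelihoods.

# Reconstruct per-observation likelihood parameters for one raw draw
# (sampling scale). Returns list(y, mu, sigma, nu, w, kind).
model_mu <- function(fit, th) {
  d <- fit$data
  if (fit$model == "vbge") {
    nL <- if (d$area_Linf) 2L else 1L
    nK <- if (d$area_K) 2L else 1L
    nT <- if (d$area_t0) 2L else 1L
    iL <- 0L; iK <- iL + nL; iT <- iK + nK; isL <- iT + nT; isK <- isL + nL
    inu <- isK + nK; isg <- inu + 1L; izL <- isg + 1L; izK <- izL + nL * d$ncoh
    aL <- if (nL == 2L) d$area else 0L
    aK <- if (nK == 2L) d$area else 0L
    aT <- if (nT == 2L) d$area else 0L
    Linf <- exp(th[iL + aL + 1L]) + exp(th[isL + aL + 1L]) *
      th[izL + aL * d$ncoh + d$coh + 1L]
    K <- exp(th[iK + aK + 1L]) + exp(th[isK + aK + 1L]) *
      th[izK + aK * d$ncoh + d$coh + 1L]
    t0 <- th[iT + aT + 1L]
    mu <- log(Linf) + log(-expm1(-K * (d$t - t0)))
    return(list(y = d$y, mu = mu, sigma = exp(th[isg + 1L]),
                nu = exp(th[inu + 1L]), w = rep(1, length(d$y)), kind = "t"))
  }
  if (fit$model == "allo") {
    nT <- if (d$area_theta) 2L else 1L
    iT <- 2L; isC <- iT + nT; isI <- isC + 1L; inu <- isI + 1L
    isg <- inu + 1L; izC <- isg + 1L; izI <- izC + d$Gc
    aT <- if (nT == 2L) d$area else 0L
    alpha <- th[d$area + 1L] + exp(th[isC + 1L]) * th[izC + d$gcoh + 1L] +
      exp(th[isI + 1L]) * th[izI + d$gid + 1L]
    mu <- alpha * exp(th[iT + aT + 1L] * d$lL)
    return(list(y = d$y, mu = mu, sigma = exp(th[isg + 1L]),
                nu = exp(th[inu + 1L]), w = rep(1, length(d$y)), kind = "t"))
  }
  if (fit$model == "cc") {
    cols <- d$cols; nb <- length(cols); re <- d$re; r <- length(re)
    ncor <- (r * (r - 1L)) %/% 2L
    itau <- nb; icor <- itau + r; inu <- icor + ncor; isg <- inu + 1L
    iz <- isg + 1L
    X <- cbind(d$heat, 1 - d$heat, d$age, d$age * d$heat)
    mu <- as.numeric(X[, cols + 1L, drop = FALSE] %*% th[seq_len(nb)])
    if (r > 0) {
      z <- tanh(th[icor + seq_len(ncor)])
      L <- diag(r)
      idx <- 1L
      for (i in seq_len(r)) if (i > 1) for (j in seq_len(i - 1L)) {
        sq <- sum(L[i, seq_len(j - 1L)]^2)
        L[i, j] <- z[idx] * sqrt(1 - sq); idx <- idx + 1L
        L[i, i] <- sqrt(max(0, 1 - sum(L[i, seq_len(i - 1L)]^2)))
      }
      tau <- exp(th[itau + seq_len(r)])
      zm <- matrix(th[iz + seq_len(d$J * r)], nrow = r) # r x J, cohort-major
      u <- (diag(tau, r) %*% L %*% zm)                  # r x J deviations
      for (c in seq_len(r))
        mu <- mu + u[c, d$coh + 1L] * X[, re[c] + 1L]
    }
    return(list(y = d$y, mu = mu, sigma = exp(th[isg + 1L]),
                nu = exp(th[inu + 1L]), w = rep(1, length(d$y)), kind = "t"))
  }
  if (fit$model == "lnorm") {
    r <- d$r
    itau <- 2L; icor <- itau + r; isg <- icor + (r == 2L); iz <- isg + 1L
    mu <- ifelse(d$heat == 1L, th[1], th[2])
    zm <- matrix(th[iz + seq_len(d$J * r)], nrow = r)
    if (r == 2L) {
      rho <- tanh(th[icor + 1L])
      u_heat <- zm[1, ]
      u_ref <- rho * zm[1, ] + sqrt(1 - rho^2) * zm[2, ]
      tau <- exp(th[itau + 1:2])
      mu <- mu + ifelse(d$heat == 1L, tau[1] * u_heat[d$yr + 1L],
                        tau[2] * u_ref[d$yr + 1L])
    } else {
      mu <- mu + exp(th[itau + 1L]) * zm[1, d$yr + 1L]
    }
    return(list(y = d$ly, mu = mu, sigma = exp(th[isg + 1L]), nu = Inf,
                w = d$w, kind = "lnorm"))
  }
  stop("unknown model")
}

# R reference pointwise log-likelihood for one raw draw (oracle for the
# compiled likelihood).
model_loglik_ref <- function(fit, th) {
  p <- model_mu(fit, th)
  if (p$kind == "t") {
    r <- (p$y - p$mu) / p$sigma
    lgamma((p$nu + 1) / 2) - lgamma(p$nu / 2) - 0.5 * log(p$nu * pi) -
      log(p$sigma) - 0.5 * (p$nu + 1) * log1p(r^2 / p$nu)
  } else {
    p$w * (stats::dnorm(p$y, p$mu, p$sigma, log = TRUE) - p$y)
  }
}

#' Posterior predictive check
#'
#' Simulates replicate datasets from the fitted model's posterior and compares
#' a test statistic of the replicates with the observed value, returning the
#' two-sided tail probability. A well-specified model gives non-extreme tail
#' probabilities; a model missing a data feature (e.g. heavy tails, with
#' `statistic = max`) gives an extreme one.
#'
#' @param fit a `tf_fit`.
#' @param statistic function of a response vector (default `mean`); applied on
#'   the model's response scale (log length, growth rate, log CPUE, log
#'   response).
#' @param ndraws number of posterior draws used.
#' @return list with `stat_obs`, `stat_rep` (vector), `p` (two-sided tail
#'   probability).
#' @export
predictive_check <- function(fit, statistic = mean, ndraws = 200L) {
  stopifnot(inherits(fit, "tf_fit"))
  S <- nrow(fit$raw)
  idx <- sample.int(S, min(ndraws, S))
  obs <- NULL
  stat_rep <- vapply(idx, function(s) {
    p <- model_mu(fit, fit$raw[s, ])
    if (is.null(obs)) obs <<- statistic(p$y)
    n <- length(p$y)
    yrep <- if (p$kind == "t") p$mu + p$sigma * stats::rt(n, p$nu)
    else stats::rnorm(n, p$mu, p$sigma)
    statistic(yrep)
  }, 0)
  p_lo <- mean(stat_rep <= obs)
  p_hi <- mean(stat_rep >= obs)
  list(stat_obs = obs, stat_rep = stat_rep, p = min(1, 2 * min(p_lo, p_hi)))
}
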