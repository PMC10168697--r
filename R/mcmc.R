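#' Sampler configuration
#'
#' Settings for the adaptive Metropolis-within-Gibbs sampler used by all model
#' fitting functions. The defaults follow the fitting contract used throughout
#' the package: three chains and 4000 iterations per chain, the first half
#' discarded as warmup during which proposal scales adapt towards a 0.44
#' acceptance rate.
#'
#' @param chains number of chains (>= 2 so that split-R-hat is defined).
#' @param iter total iterations per chain, including warmup.
#' @param warmup iterations discarded as warmup; defaults to `iter / 2`.
#' @param thin keep every `thin`-th post-warmup draw (reduces autocorrelation
#'   in the stored sample at fixed memory).
#' @param target_accept target acceptance rate for the coordinate-wise
#'   Gaussian proposals (0.44 is standard for one-dimensional updates).
#' @return a list of class `tf_sampler_config`.
#' @export
sampler_config <- function(chains = 3L, iter = 4000L, warmup = NULL,
                           thin = 1L, target_accept = 0.44) {
  chains <- as.integer(chains)
  iter <- as.integer(iter)
  if (is.null(warmup)) warmup <- iter %/% 2L
  warmup <- as.integer(warmup)
  thin <- as.integer(thin)
  stopifnot(chains >= 1L, iter > warmup, warmup >= 0L, thin >= 1L,
            target_accept > 0, target_accept < 1)
  structure(list(chains = chains, iter = iter, warmup = warmup, thin = thin,
                 target_accept = target_accept),
            class = "tf_sampler_config")
}

# Run the C++ AMWG sampler for one model and assemble a tf_fit object.
#
# model      : one of "vbge", "allo", "cc", "lnorm"
# data       : the data list the C++ side expects
# init       : numeric vector of initial values on the sampling scale
# scale0     : initial proposal scales (length d or 1)
# pars       : parameter names, length d
# transform  : "identity" or "exp" per parameter (reporting scale)
# spec       : free-form list describing the model variant (stored)
run_mcmc <- function(model, data, init, scale0, pars, transform,
                     config = sampler_config(), spec = list(), seed = NULL,
                     blocks = NULL, shift_fam = list(), scale_fam = list()) {
  d <- length(init)
  stopifnot(length(pars) == d, length(transform) == d)
  if (length(scale0) == 1L) scale0 <- rep(scale0, d)
  # joint-update blocks: always one over the global (non-group) parameters,
  # plus any model-supplied blocks of correlated group deviations
  globals <- which(!grepl("^z", pars)) - 1L
  blocks <- c(list(globals), lapply(blocks, as.integer))
  if (!is.null(seed)) set.seed(seed)
  keep <- (config$iter - config$warmup + config$thin - 1L) %/% config$thin
  raw <- vector("list", config$chains)
  accept <- matrix(NA_real_, d, config$chains)
  for (ch in seq_len(config$chains)) {
    init_ch <- init + stats::rnorm(d, 0, scale0)
    res <- .amwg_chain(model, data, init_ch, scale0, config$iter,
                       config$warmup, config$target_accept, config$thin,
                       blocks, shift_fam, scale_fam)
    raw[[ch]] <- res$draws
    accept[, ch] <- res$accept
  }
  draws <- array(NA_real_, c(keep, config$chains, d),
                 dimnames = list(NULL, NULL, pars))
  for (ch in seq_len(config$chains)) {
    m <- raw[[ch]]
    for (p in seq_len(d)) {
      draws[, ch, p] <- switch(transform[p],
                               exp = exp(m[, p]),
                               tanh = tanh(m[, p]),
                               m[, p])
    }
  }
  fit <- structure(list(
    model = model, data = data, spec = spec, pars = pars,
    transform = transform, draws = draws,
    raw = do.call(rbind, raw), sampler = config,
    accept = rowMeans(accept)
  ), class = "tf_fit")
  fit$rhat <- apply(draws, 3, split_rhat)
  fit
}

#' Extract posterior draws of a parameter
#'
#' @param fit a `tf_fit` object.
#' @param par parameter name (see `fit$pars`), or NULL for the full
#'   draws-by-parameter matrix.
#' @return numeric vector of draws pooled across chains (reporting scale), or
#'   a matrix if `par` is NULL.
#' @export
posterior_draws <- function(fit, par = NULL) {
  stopifnot(inherits(fit, "tf_fit"))
  dm <- dim(fit$draws)
  m <- matrix(fit$draws, dm[1] * dm[2], dm[3],
              dimnames = list(NULL, fit$pars))
  if (is.null(par)) return(m)
  if (!par %in% fit$pars) stop("unknown parameter: ", par)
  m[, par]
}

#' Summarize a fitted model
#'
#' Posterior medians with central 50/90/95% credible intervals and split-R-hat
#' per parameter. Intervals are nested by construction (central quantiles).
#'
#' @param object a `tf_fit`.
#' @param pars optional subset of parameter names.
#' @param ... unused.
#' @return a data.frame with one row per parameter.
#' @export
summary.tf_fit <- function(object, pars = NULL, ...) {
  if (is.null(pars)) pars <- object$pars
  m <- posterior_draws(object)[, pars, drop = FALSE]
  q <- t(apply(m, 2, stats::quantile,
               probs = c(0.5, 0.25, 0.75, 0.05, 0.95, 0.025, 0.975)))
  out <- data.frame(
    parameter = pars, median = q[, 1],
    l50 = q[, 2], u50 = q[, 3], l90 = q[, 4], u90 = q[, 5],
    l95 = q[, 6], u95 = q[, 7], rhat = object$rhat[pars],
    row.names = NULL
  )
  out
}

#' @export
print.tf_fit <- function(x, ...) {
  cat("thermofish MCMC fit: model '", x$model, "', ",
      dim(x$draws)[2], " chains x ", dim(x$draws)[1], " draws, ",
      length(x$pars), " parameters\n", sep = "")
  cat("max split-R-hat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  hyper <- x$pars[!grepl("^z", x$pars)]
  print(summary(x, pars = hyper), digits = 3)
  invisible(x)
}

# Classic split-R-hat for one parameter given a (draws x chains) matrix.
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  seqs <- cbind(x[seq_len(half), , drop = FALSE],
                x[(n - half + 1L):n, , drop = FALSE])
  mns <- colMeans(seqs)
  vars <- apply(seqs, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (!is.finite(W) || W <= 0) return(if (B == 0 || !is.finite(B)) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence check
#'
#' Computes split-R-hat for every parameter and flags the fit as converged only
#' if all values are below the threshold (mixing of all chains to a common
#' distribution).
#'
#' @param fit a `tf_fit`.
#' @param threshold R-hat threshold, default 1.1.
#' @return list with `rhat` (named vector, one entry per parameter), `pass`
#'   (logical), `failed` (parameter names at or above the threshold).
#' @export
check_convergence <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "tf_fit"))
  if (dim(fit$draws)[2] < 2L)
    stop("convergence diagnostics need at least 2 chains")
  rh <- fit$rhat
  failed <- names(rh)[!is.na(rh) & rh >= threshold]
  list(rhat = rh, pass = length(failed) == 0L, threshold = threshold,
       failed = failed)
}

# Pointwise log-likelihood matrix (draws x observations) for a fitted model,
# optionally thinned to at most max_draws rows.
pointwise_loglik <- function(fit, max_draws = 1000L) {
  stopifnot(inherits(fit, "tf_fit"))
  S <- nrow(fit$raw)
  idx <- if (S > max_draws) round(seq(1L, S, length.out = max_draws)) else seq_len(S)
  .model_loglik(fit$model, fit$data, fit$raw[idx, , drop = FALSE])
}
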