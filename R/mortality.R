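# Mortality estimation: age-length keys, catch-at-age expansion, descending
# limb selection and Bayesian catch-curve regression.

#' Build an age-length key
#'
#' Tabulates the aged subsample into a matrix of conditional age proportions
#' per length class: rows are length classes (lower edges on the class grid),
#' columns are ages, and each row with data sums to 1.
#'
#' @param aged_fish data.frame with `length_at_catch`, `age` and `area`.
#' @param area optional area filter (`"heat"` or `"ref"`).
#' @param class_width length class width in cm (default 2.5).
#' @return object of class `tf_alk`: list with `area`, `class_width`,
#'   `classes` (lower edges), `ages`, `prop` (proportion matrix) and `n`
#'   (aged fish per class).
#' @export
build_alk <- function(aged_fish, area = NULL, class_width = 2.5) {
  stopifnot(all(c("length_at_catch", "age") %in% names(aged_fish)))
  if (!is.null(area)) aged_fish <- aged_fish[aged_fish$area == area, , drop = FALSE]
  if (nrow(aged_fish) == 0L)
    stop("no aged fish", if (!is.null(area)) paste0(" in area '", area, "'"))
  lower <- floor(aged_fish$length_at_catch / class_width) * class_width
  ages <- sort(unique(aged_fish$age))
  classes <- sort(unique(lower))
  tab <- table(factor(lower, levels = classes),
               factor(aged_fish$age, levels = ages))
  n <- rowSums(tab)
  prop <- sweep(unclass(tab), 1, pmax(n, 1), "/")
  prop[n == 0, ] <- NA_real_
  structure(list(area = area, class_width = class_width,
                 classes = classes, ages = as.integer(ages),
                 prop = prop, n = as.integer(n)),
            class = "tf_alk")
}

#' Expand binned catch to catch-at-age CPUE
#'
#' Distributes the counts of each length class over ages using the area's
#' age-length key and divides by effort (net-nights, the number of distinct
#' net deployments per area and year) to give CPUE-at-age. Total fish are
#' conserved: summed over ages, `cpue * effort` equals the summed counts.
#' A catch class missing from the key borrows the nearest class within one
#' class width; a class with no such neighbour is an error.
#'
#' @param catch data.frame of catch records (`area`, `year`, `net_id`,
#'   `length_class_lower`, `length_class_width`, `count`); widths must match
#'   the key's grid (use [rebin_catch()] for 1 cm years first).
#' @param alk a `tf_alk` from [build_alk()].
#' @return data.frame `area`, `year`, `age`, `cohort`, `cpue`, with the
#'   effort table as attribute `"effort"`.
#' @export
expand_catch <- function(catch, alk) {
  stopifnot(inherits(alk, "tf_alk"), nrow(catch) > 0)
  if (!is.null(alk$area)) catch <- catch[catch$area == alk$area, , drop = FALSE]
  if (nrow(catch) == 0L) stop("no catch records for the key's area")
  if (any(catch$length_class_width != alk$class_width))
    stop("catch class width differs from the key's grid (",
         alk$class_width, " cm); rebin first with rebin_catch()")
  has_data <- which(!is.na(alk$prop[, 1]))
  if (length(has_data) == 0L) stop("age-length key has no informative rows")
  row_for_class <- function(lc) {
    i <- match(lc, alk$classes)
    if (!is.na(i) && !is.na(alk$prop[i, 1])) return(i)
    d <- abs(alk$classes[has_data] - lc)
    j <- has_data[which.min(d)]
    if (min(d) > alk$class_width + 1e-9)
      stop("catch class [", lc, ", ", lc + alk$class_width,
           ") has no age-length key row and no adjacent neighbour")
    j
  }
  out <- list()
  for (ay in split(catch, list(catch$area, catch$year), drop = TRUE)) {
    effort <- length(unique(ay$net_id))
    counts <- tapply(ay$count, ay$length_class_lower, sum)
    at_age <- numeric(length(alk$ages))
    for (k in seq_along(counts)) {
      lc <- as.numeric(names(counts))[k]
      at_age <- at_age + counts[[k]] * alk$prop[row_for_class(lc), ]
    }
    out[[length(out) + 1L]] <- data.frame(
      area = ay$area[1], year = ay$year[1], age = alk$ages,
      cohort = ay$year[1] - alk$ages,
      cpue = as.numeric(at_age) / effort, effort = effort
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  eff <- unique(res[, c("area", "year", "effort")])
  res$effort <- NULL
  attr(res, "effort") <- eff
  res
}

#' Rebin 1 cm catch classes to the 2.5 cm grid
#'
#' Converts catch recorded in 1 cm length classes to the common 2.5 cm class
#' standard by proportional width-overlap allocation (a 1 cm class straddling
#' a 2.5 cm boundary is split between the two target classes in proportion to
#' the overlap). Rows already on the target grid pass through; counts may
#' become non-integer.
#'
#' @param catch data.frame of catch records.
#' @param target_width target class width (default 2.5).
#' @return catch records on the target grid.
#' @export
rebin_catch <- function(catch, target_width = 2.5) {
  done <- catch[catch$length_class_width == target_width, , drop = FALSE]
  todo <- catch[catch$length_class_width != target_width, , drop = FALSE]
  if (nrow(todo) == 0L) return(catch)
  pieces <- list()
  for (i in seq_len(nrow(todo))) {
    lo <- todo$length_class_lower[i]
    hi <- lo + todo$length_class_width[i]
    t_lo <- floor(lo / target_width) * target_width
    while (t_lo < hi) {
      ov <- min(hi, t_lo + target_width) - max(lo, t_lo)
      if (ov > 0) {
        row <- todo[i, ]
        row$length_class_lower <- t_lo
        row$length_class_width <- target_width
        row$count <- todo$count[i] * ov / (hi - lo)
        pieces[[length(pieces) + 1L]] <- row
      }
      t_lo <- t_lo + target_width
    }
  }
  out <- rbind(done, do.call(rbind, pieces))
  agg <- stats::aggregate(
    count ~ area + year + net_id + length_class_lower + length_class_width,
    data = out, FUN = sum
  )
  agg[order(agg$area, agg$year, agg$net_id, agg$length_class_lower), ]
}

#' Drop disturbed fishing events
#'
#' Removes catch records flagged as disturbed (e.g. seal damage or algal
#' clogging of the gear); a no-op if the column is absent.
#'
#' @param catch catch records, optionally with a logical `disturbed` column.
#' @return filtered catch records.
#' @export
filter_disturbed <- function(catch) {
  if (!"disturbed" %in% names(catch)) return(catch)
  catch[!catch$disturbed, setdiff(names(catch), "disturbed"), drop = FALSE]
}

#' Select the descending limb of the catch curve
#'
#' Because the smallest and youngest fish are not representatively caught by
#' the gear, the catch is dome-shaped over age; only ages at and beyond the
#' catch mode are informative about mortality. The modal age is computed per
#' area on year-pooled mean CPUE, and ages >= the mode are retained.
#'
#' @param catch_at_age data.frame from [expand_catch()].
#' @return filtered data.frame; attribute `"modal_age"` records the criterion
#'   per area.
#' @export
select_descending_limb <- function(catch_at_age) {
  stopifnot(nrow(catch_at_age) > 0)
  if (all(catch_at_age$cpue == 0)) stop("all CPUE values are zero")
  keep <- logical(nrow(catch_at_age))
  modal <- list()
  for (a in unique(catch_at_age$area)) {
    sel <- catch_at_age$area == a
    mu <- tapply(catch_at_age$cpue[sel], catch_at_age$age[sel], mean)
    mode_age <- as.numeric(names(mu))[which.max(mu)]
    modal[[a]] <- mode_age
    keep[sel] <- catch_at_age$age[sel] >= mode_age
  }
  out <- catch_at_age[keep, , drop = FALSE]
  attr(out, "modal_age") <- unlist(modal)
  out
}

#' Bayesian catch-curve regression
#'
#' Fits `log(CPUE) ~ t(nu, mu, sigma)` with
#' `mu = b0 * heat + b1 * ref + b2 * age + b3 * age * heat` (the interaction
#' term optional), so the instantaneous mortality rates are `Z_ref = -b2` and
#' `Z_heat = -(b2 + b3)`. Coefficients can vary by cohort (or year) under a
#' correlated multivariate-normal prior with estimated correlations:
#' `cohort_effects = "full"` lets all coefficients vary, `"intercept"` only
#' the two area intercepts, `"none"` fits fixed effects only. Regression
#' coefficients get flat priors; `nu ~ Gamma(2, 0.1)`; scales and group SDs
#' half-Student-t(3, 0, 2.5); partial correlations uniform via a tanh
#' transform.
#'
#' Zero-CPUE rows are dropped before taking logs (with a message).
#'
#' @param catch_at_age data.frame with `area`, `year`, `age`, `cpue` (and
#'   `cohort`; recomputed as `year - age` if absent).
#' @param interaction include the age-by-area interaction (area-specific Z).
#' @param cohort_effects which coefficients vary by group.
#' @param group grouping variable for the varying coefficients.
#' @param config a [sampler_config()].
#' @param seed optional seed.
#' @return a `tf_fit`; extract mortality draws with [mortality_Z()].
#' @export
fit_catch_curve <- function(catch_at_age, interaction = TRUE,
                            cohort_effects = c("intercept", "full", "none"),
                            group = c("cohort", "year"),
                            config = sampler_config(), seed = NULL) {
  cohort_effects <- match.arg(cohort_effects)
  group <- match.arg(group)
  stopifnot(all(c("area", "year", "age", "cpue") %in% names(catch_at_age)))
  if (is.null(catch_at_age$cohort))
    catch_at_age$cohort <- catch_at_age$year - catch_at_age$age
  nzero <- sum(catch_at_age$cpue <= 0)
  if (nzero > 0) {
    message("dropping ", nzero, " zero/negative CPUE row(s) before log")
    catch_at_age <- catch_at_age[catch_at_age$cpue > 0, , drop = FALSE]
  }
  for (a in unique(catch_at_age$area)) {
    nage <- length(unique(catch_at_age$age[catch_at_age$area == a]))
    if (nage < 3L)
      stop("area '", a, "' has ", nage,
           " distinct ages; the age slope is unidentifiable")
  }
  heat <- as.integer(catch_at_age$area == "heat")
  single_area <- length(unique(catch_at_age$area)) == 1L
  gvar <- if (group == "cohort") catch_at_age$cohort else catch_at_age$year
  glev <- sort(unique(gvar))
  # design columns: 0 = heat intercept, 1 = ref intercept, 2 = age,
  # 3 = age x heat interaction
  cols <- if (single_area) c(if (all(heat == 1L)) 0L else 1L, 2L)
  else if (interaction) 0:3 else 0:2
  re <- switch(cohort_effects,
               none = integer(0),
               intercept = intersect(cols, 0:1),
               full = cols)
  data <- list(y = log(catch_at_age$cpue),
               age = as.numeric(catch_at_age$age),
               heat = heat, coh = match(gvar, glev) - 1L,
               J = length(glev), cols = as.integer(cols),
               re = as.integer(re))
  nb <- length(cols)
  # initial values from the ordinary least-squares catch curve
  Xall <- cbind(heat, 1 - heat, data$age, data$age * heat)
  X <- Xall[, cols + 1L, drop = FALSE]
  b0 <- tryCatch(stats::lm.fit(X, data$y)$coefficients, error = function(e) NULL)
  if (is.null(b0)) b0 <- c(5, -0.5)[seq_len(nb)]
  b0[is.na(b0)] <- 0
  r <- length(re); ncor <- (r * (r - 1L)) %/% 2L
  fulln <- c("b_int_heat", "b_int_ref", "b_age", "b_age_heat")
  bn <- fulln[cols + 1L]
  ren <- fulln[re + 1L]
  corn <- if (ncor > 0)
    utils::combn(ren, 2, function(p) paste0("rho[", p[2], ",", p[1], "]"))
  else character(0)
  zn <- if (r > 0) paste0("z[", rep(glev, each = r), ",", ren, "]") else character(0)
  pars <- c(bn, if (r > 0) paste0("tau_", ren), corn, "nu", "sigma", zn)
  transform <- c(rep("identity", nb), rep("exp", r), rep("tanh", ncor),
                 "exp", "exp", rep("identity", length(zn)))
  init <- c(as.numeric(b0), rep(log(0.3), r), rep(0, ncor), log(10),
            log(max(0.1, stats::sd(data$y - X %*% b0))), rep(0, length(zn)))
  scale0 <- c(rep(0.1, nb), rep(0.2, r), rep(0.3, ncor), 0.3, 0.1,
              rep(0.3, length(zn)))
  run_mcmc("cc", data, init, scale0, pars, transform, config,
           spec = list(model = "cc", interaction = nb == 4L,
                       cohort_effects = cohort_effects, group = group,
                       groups = glev, single_area = single_area),
           seed = seed)
}

#' Mortality draws from a catch-curve fit
#'
#' @param fit a `tf_fit` from [fit_catch_curve()].
#' @return list with draw vectors `Z_heat`, `Z_ref` (equal when the model has
#'   no age-by-area interaction) and `diff = Z_heat - Z_ref`.
#' @export
mortality_Z <- function(fit) {
  stopifnot(inherits(fit, "tf_fit"), fit$spec$model == "cc")
  b2 <- posterior_draws(fit, "b_age")
  Z_ref <- -b2
  Z_heat <- if (fit$spec$interaction) -(b2 + posterior_draws(fit, "b_age_heat"))
  else Z_ref
  list(Z_heat = Z_heat, Z_ref = Z_ref, diff = Z_heat - Z_ref)
}

#' Annual mortality from instantaneous mortality
#'
#' `1 - exp(-Z)`, the fraction of a cohort dying per year.
#'
#' @param Z instantaneous mortality rate (1/yr), finite.
#' @return fraction in `[0, 1)` (vectorized).
#' @export
annual_mortality <- function(Z) {
  if (any(!is.finite(Z))) stop("'Z' must be finite")
  -expm1(-Z)
}

#' Ordinary least-squares catch curve (cross-check)
#'
#' Classic log-linear catch-curve regression per area, `log(cpue) ~ age`;
#' the negative slope estimates Z. Used as a frequentist cross-check of the
#' Bayesian fit.
#'
#' @param catch_at_age data.frame with `area`, `age`, `cpue` (> 0 rows used).
#' @return named vector of Z point estimates per area.
#' @export
catch_curve_lm <- function(catch_at_age) {
  catch_at_age <- catch_at_age[catch_at_age$cpue > 0, , drop = FALSE]
  vapply(split(catch_at_age, catch_at_age$area), function(d)
    -unname(stats::coef(stats::lm(log(cpue) ~ age, data = d))[2]), 0)
}
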