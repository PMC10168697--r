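#' Back-calculate lengths-at-age from operculum radii
#'
#' Uses the power-law relation between fish length and operculum radius,
#' `L = kappa * R^s`: the length at age `a` is `L_a = L_s * (r_a / R)^s`,
#' where `L_s` is the length at catch, `R` the operculum radius at catch (the
#' last radius) and `r_a` the radius at annulus `a`. The intercept `kappa`
#' cancels, so only the exponent `s` is needed (default 0.861, the published
#' value for perch).
#'
#' @param L_s length at catch (cm), positive scalar.
#' @param radii strictly increasing annulus radii; the last element is the
#'   radius at catch.
#' @param s back-calculation exponent (> 0).
#' @return numeric vector of back-calculated lengths, one per radius,
#'   monotone increasing with last element equal to `L_s`.
#' @export
backcalc_lengths <- function(L_s, radii, s = 0.861) {
  if (!is.numeric(L_s) || length(L_s) != 1L || L_s <= 0)
    stop("'L_s' must be a positive scalar length")
  if (s <= 0) stop("'s' must be positive")
  if (length(radii) < 1L || any(radii <= 0))
    stop("'radii' must be positive")
  if (any(diff(radii) <= 0))
    stop("'radii' must be strictly increasing")
  R <- radii[length(radii)]
  L_s * (radii / R)^s
}

#' Annual specific growth observations from aged fish
#'
#' Back-calculates each fish's length-at-age from its annulus radii and
#' converts consecutive ages into annual specific growth rates
#' `G = 100 * (log(L_{t+1}) - log(L_t))` (%/yr, natural logs), paired with the
#' geometric mean length `L_geo = sqrt(L_t * L_{t+1})` of the interval. A fish
#' of age `a` yields `a - 1` observations; fish with fewer than two radii are
#' skipped with a warning.
#'
#' @param records data.frame from [simulate_cohorts()] (columns `id`, `area`,
#'   `cohort`, `length_at_catch` and list-column `radii`).
#' @param s back-calculation exponent.
#' @return data.frame with `id`, `area`, `cohort`, `age_start`, `L_start`,
#'   `L_end`, `G`, `L_geo`.
#' @export
growth_observations <- function(records, s = 0.861) {
  stopifnot(is.data.frame(records), "radii" %in% names(records))
  nrad <- lengths(records$radii)
  if (any(nrad < 2L)) {
    warning(sum(nrad < 2L), " record(s) with fewer than 2 radii skipped")
    records <- records[nrad >= 2L, , drop = FALSE]
  }
  if (nrow(records) == 0L)
    return(data.frame(id = integer(), area = character(), cohort = integer(),
                      age_start = integer(), L_start = numeric(),
                      L_end = numeric(), G = numeric(), L_geo = numeric()))
  out <- vector("list", nrow(records))
  for (k in seq_len(nrow(records))) {
    L <- backcalc_lengths(records$length_at_catch[k], records$radii[[k]], s)
    a <- length(L)
    out[[k]] <- data.frame(
      id = records$id[k], area = records$area[k], cohort = records$cohort[k],
      age_start = seq_len(a - 1L),
      L_start = L[-a], L_end = L[-1],
      G = 100 * (log(L[-1]) - log(L[-a])),
      L_geo = sqrt(L[-a] * L[-1])
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
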