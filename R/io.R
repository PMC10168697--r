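# CSV and YAML input/output. Fish tables are written as two CSVs (one row per
# fish, plus a long table of annulus radii) so everything stays plain text.

#' Write fish and catch tables as CSV
#'
#' `fish.csv` holds one row per fish (no radii); `radii.csv` is a long table
#' `(id, annulus, radius)`; `catch.csv` the binned catch records. UTF-8,
#' header row, '.' decimal.
#'
#' @param fish fish table (may be NULL).
#' @param catch catch table (may be NULL).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_tables <- function(fish = NULL, catch = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(fish)) {
    flat <- fish[setdiff(names(fish), "radii")]
    p1 <- file.path(dir, "fish.csv")
    utils::write.csv(flat, p1, row.names = FALSE)
    paths <- c(paths, p1)
    if (!is.null(fish$radii)) {
      long <- data.frame(
        id = rep(fish$id, lengths(fish$radii)),
        annulus = unlist(lapply(fish$radii, seq_along)),
        radius = unlist(fish$radii)
      )
      p2 <- file.path(dir, "radii.csv")
      utils::write.csv(long, p2, row.names = FALSE)
      paths <- c(paths, p2)
    }
  }
  if (!is.null(catch)) {
    p3 <- file.path(dir, "catch.csv")
    utils::write.csv(catch, p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Read fish and catch tables written by [write_tables()]
#'
#' @param dir directory holding `fish.csv` (+ optional `radii.csv`) and/or
#'   `catch.csv`.
#' @return list with `fish` and `catch` (NULL when absent).
#' @export
read_tables <- function(dir) {
  out <- list(fish = NULL, catch = NULL)
  fp <- file.path(dir, "fish.csv")
  if (file.exists(fp)) {
    fish <- utils::read.csv(fp)
    rp <- file.path(dir, "radii.csv")
    if (file.exists(rp)) {
      long <- utils::read.csv(rp)
      long <- long[order(long$id, long$annulus), ]
      fish$radii <- I(unname(split(long$radius, factor(long$id, levels = fish$id))))
    }
    out$fish <- fish
  }
  cp <- file.path(dir, "catch.csv")
  if (file.exists(cp)) out$catch <- utils::read.csv(cp)
  out
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `sim`, `sampler` and any [pipeline_config()] argument;
#' entries under `sim`/`sampler` are passed to [sim_config()] /
#' [sampler_config()]. Absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("sim", "sampler"))]
  simplify_area <- function(x) if (is.list(x)) unlist(x) else x
  if (!is.null(y$sim))
    args$sim <- do.call(sim_config, lapply(y$sim, simplify_area))
  if (!is.null(y$sampler)) args$sampler <- do.call(sampler_config, y$sampler)
  if (!is.null(args$stages)) args$stages <- unlist(args$stages)
  do.call(pipeline_config, args)
}

# Write pipeline outputs (tables as CSV, report as JSON, config as YAML).
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tables(res$fish, res$catch, dir)
  if (!is.null(res$aged)) write_tables(res$aged, NULL, file.path(dir, "aged"))
  if (!is.null(res$catch_at_age))
    utils::write.csv(res$catch_at_age, file.path(dir, "catch_at_age.csv"),
                     row.names = FALSE)
  for (nm in intersect(c("vbge", "growth", "catch_curve", "mean_size",
                         "mean_age"), names(res))) {
    utils::write.csv(summary(res[[nm]]),
                     file.path(dir, paste0("posterior_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- res$config
  yaml::write_yaml(list(seed = cfg$seed,
                        n_aged_per_area = cfg$n_aged_per_area,
                        stages = as.list(cfg$stages)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
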