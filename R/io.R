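# ---------------------------------------------------------------------------
# Run configuration, pipelines, fixtures, metadata
# ---------------------------------------------------------------------------

config_schema <- list(
  seed = NULL,
  geometry = c("patch_area_m2", "reach_m", "n_trials"),
  lightning = c("density_km2_yr", "merge_factor", "stochastic_kills",
                "rate_table"),
  demography = c("disturbance_interval_yr", "hazard_baseline", "hazard_slope",
                 "hazard_exp", "establishment_density_m2", "establishment_cai",
                 "establishment_min_gap_yr", "self_thinning_cai",
                 "crown_r0_m", "crown_r_slope", "establishment_pfts",
                 "prune_density_m2"),
  climatology = c("resolution_deg", "period"),
  io = c("out_dir")
)

#' Read and validate a run configuration
#'
#' YAML file with optional sections `seed`, `geometry`, `lightning`,
#' `demography`, `climatology`, `io`. Unknown sections or keys are
#' rejected so typos fail loudly instead of silently running defaults.
#'
#' @param path YAML file path.
#' @return validated configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in setdiff(names(cfg), "seed")) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad) > 0) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

build_from_config <- function(cfg, section, constructor) {
  args <- cfg[[section]]
  if (is.null(args)) args <- list()
  do.call(constructor, args)
}

config_rate_table <- function(cfg) {
  spec <- cfg$lightning$rate_table
  if (is.null(spec) || identical(spec, "synthetic")) return(synthetic_rate_table())
  read_rate_table_csv(spec)
}

#' Write a run metadata sidecar
#'
#' Records the configuration (and its MD5 hash), seed, package version
#' and R version next to a run's outputs so any output file can be traced
#' back to the exact inputs that produced it.
#'
#' @param path output JSON path.
#' @param cfg the configuration list used.
#' @param seed the seed used.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, cfg, seed) {
  tmp <- tempfile()
  yaml::write_yaml(unclass(cfg), tmp)
  meta <- list(
    config = unclass(cfg),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    package_version = as.character(utils::packageVersion("strikesim")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  unlink(tmp)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Pipelines
# ---------------------------------------------------------------------------

#' Estimate mortality rates from survey and census files
#'
#' @param survey_csv,census_csv input file paths.
#' @param out_csv output rate-table path.
#' @param min_days qualifying-survey threshold (days).
#' @return the `mortality_rate_table`, invisibly; a report of scope
#'   sizes is printed via `message()`.
#' @export
run_estimate_rates <- function(survey_csv, census_csv, out_csv,
                               min_days = 346) {
  survey <- read_strike_survey_csv(survey_csv)
  census <- read_census_csv(census_csv)
  cfg <- estimation_config(min_days)
  sets <- filter_strikes(survey, cfg)
  message(sprintf("neighbour scope: %d strikes; direct scope: %d strikes",
                  length(sets$neighbour), length(sets$direct)))
  tab <- estimate_rates(survey, census, cfg)
  write_rate_table_csv(tab, out_csv)
  invisible(tab)
}

#' Simulate a stand under lightning and demography
#'
#' @param config a validated `run_config` (or path to one).
#' @param stand_csv optional stand description CSV; if `NULL` a
#'   synthetic stand is generated from `profile`.
#' @param profile profile for [gen_stand()] when `stand_csv` is `NULL`.
#' @param years simulated years.
#' @param out_dir output directory (trajectory.csv, ledger.csv,
#'   metadata.json); `NULL` writes nothing.
#' @return the [run_stand_simulation()] result, invisibly.
#' @export
run_simulate_stand <- function(config, stand_csv = NULL, profile = "bci_like",
                               years = 200, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- if (is.null(config$seed)) 1 else config$seed
  geom <- build_from_config(config, "geometry", geometry_config)
  demog <- build_from_config(config, "demography", demography_config)
  lcfg_args <- config$lightning
  density <- if (is.null(lcfg_args$density_km2_yr)) 0 else lcfg_args$density_km2_yr
  merge_f <- if (is.null(lcfg_args$merge_factor)) 5 else lcfg_args$merge_factor
  lcfg <- lightning_config(config_rate_table(config),
                           isTRUE(lcfg_args$stochastic_kills))

  group <- if (is.null(stand_csv)) {
    gen_stand(profile, seed = seed, n_patches = merge_f)
  } else {
    read_stand_csv(stand_csv)
  }
  lightning <- if (density > 0) {
    list(density_km2_yr = density, cfg = lcfg, geom = geom)
  }
  res <- run_stand_simulation(group, years, demog, lightning, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$trajectory, file.path(out_dir, "trajectory.csv"),
                     row.names = FALSE)
    write_ledger_csv(res$ledger, res$group, file.path(out_dir, "ledger.csv"))
    write_run_metadata(file.path(out_dir, "metadata.json"), config, seed)
  }
  invisible(res)
}

#' Expected lightning kills over a density grid
#'
#' Deterministic upscaling: per cell, expected kills per patch-year are
#' the expected annual strike count times the per-strike kill
#' expectation of the stand profile ([kills_per_strike_expectation()]),
#' scaled to kills per km2 of natural land per year and by the
#' natural-land fraction for cell totals.
#'
#' @param grid a [density_grid()] of CG lightning (or path to its CSV).
#' @param config a validated `run_config` (or path).
#' @param profile stand profile applied everywhere.
#' @param natural_fraction scalar or matrix (grid-shaped) natural-land
#'   fraction.
#' @param min_diameter_cm count only kills of at least this stem size.
#' @param out_csv optional output path (long format per-cell totals).
#' @return data frame with per-cell `kills_per_km2_yr` and
#'   `kills_per_yr` (cell total over natural land), invisibly if written.
#' @export
run_simulate_grid <- function(grid, config, profile = "bci_like",
                              natural_fraction = 1, min_diameter_cm = 1,
                              out_csv = NULL) {
  if (is.character(grid)) grid <- read_grid_csv(grid)
  if (is.character(config)) config <- read_run_config(config)
  seed <- if (is.null(config$seed)) 1 else config$seed
  geom <- build_from_config(config, "geometry", geometry_config)
  merge_f <- if (is.null(config$lightning$merge_factor)) 5 else config$lightning$merge_factor
  lcfg <- lightning_config(config_rate_table(config))
  group <- gen_stand(profile, seed = seed, n_patches = merge_f)
  exp_kill <- kills_per_strike_expectation(group, lcfg, geom)
  keep <- size_classes()$lower_cm >= min_diameter_cm
  kills_per_strike <- sum(exp_kill$per_size[keep])

  if (is.matrix(natural_fraction)) {
    stopifnot(all(dim(natural_fraction) == dim(grid$density)))
    nf <- natural_fraction
  } else {
    nf <- matrix(natural_fraction, length(grid$lat), length(grid$lon))
  }
  # strikes per patch-year = density * extended area; kills per m2 of
  # natural land per year = strikes * kills_per_strike / patch area
  lambda <- grid$density * geom$extended_area_m2 / 1e6
  kills_m2 <- lambda * kills_per_strike / geom$patch_area_m2
  area_km2 <- matrix(cell_area_km2(grid$lat, grid$resolution_deg),
                     length(grid$lat), length(grid$lon))
  out <- data.frame(
    lat = rep(grid$lat, times = length(grid$lon)),
    lon = rep(grid$lon, each = length(grid$lat)),
    density_km2_yr = as.vector(grid$density),
    natural_fraction = as.vector(nf),
    kills_per_km2_yr = as.vector(kills_m2 * 1e6),
    kills_per_yr = as.vector(kills_m2 * 1e6 * area_km2 * nf))
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write a complete worked-example fixture directory
#'
#' Generates a synthetic stand, strike survey + census, rate table,
#' flash records, a small density grid and a run config, all as plain
#' text, so every pipeline stage can be exercised from files.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @return named list of the written paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  group <- gen_stand("bci_like", seed = seed)
  paths$stand <- file.path(dir, "stand.csv")
  write_stand_csv(group, paths$stand)

  sv <- gen_strike_survey(n_strikes = 60, seed = seed)
  paths$survey <- file.path(dir, "survey.csv")
  paths$census <- file.path(dir, "census.csv")
  utils::write.csv(sv$survey, paths$survey, row.names = FALSE)
  utils::write.csv(sv$census, paths$census, row.names = FALSE)

  paths$rate_table <- file.path(dir, "rate_table_synthetic.csv")
  write_rate_table_csv(synthetic_rate_table(), paths$rate_table)

  # a small 4 x 4 half-degree window at modest intensity keeps the
  # worked example light-weight
  lat <- seq(8.25, 9.75, by = 0.5)
  lon <- seq(-80.75, -79.25, by = 0.5)
  set.seed(seed)
  intensity <- matrix(stats::runif(length(lat) * length(lon), 0, 0.1),
                      length(lat), length(lon))
  igrid <- density_grid(lat, lon, intensity, 0.5)
  rec <- gen_flash_records(igrid, years = 2, seed = seed)
  paths$flash_records <- file.path(dir, "flash_records.csv")
  utils::write.csv(rec, paths$flash_records, row.names = FALSE)
  cg <- grid_flash_climatology(rec, resolution_deg = 0.5,
                               period = c("2016-01-01", "2017-12-31"),
                               lat_range = c(8, 10), lon_range = c(-81, -79))
  paths$grid <- file.path(dir, "cg_density_grid.csv")
  write_grid_csv(cg, paths$grid)

  cfg <- list(seed = seed,
              geometry = list(patch_area_m2 = 1000, reach_m = 45),
              lightning = list(density_km2_yr = 12.7, merge_factor = 5,
                               rate_table = "synthetic"),
              demography = list(disturbance_interval_yr = 150))
  paths$config <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
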