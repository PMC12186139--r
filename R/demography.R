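# ---------------------------------------------------------------------------
# Minimal cohort demography: growth, background mortality, disturbance,
# establishment, and cause-attributed mortality ledgers
# ---------------------------------------------------------------------------

mortality_causes <- c("lightning", "background", "disturbance",
                      "self_thinning", "fire")

#' Demography configuration
#'
#' An explicitly simplified cohort demography engine: logistic-style
#' diameter growth, an age-dependent background mortality hazard,
#' stand-destroying generic disturbances at a prescribed mean return
#' interval, a density-dependent self-thinning term (standing in for
#' light-competition mortality), and light-proxied establishment that
#' adds new cohorts when crown cover falls below a threshold.
#'
#' The background hazard is `h(age) = (b0 + b1 (age/L)^p) / L` per year
#' with `L` the PFT longevity; the default slope `b1 = 1.832` (with
#' `b0 = 0.2`, `p = 4`) makes the mean age at death equal `L`.
#'
#' @param disturbance_interval_yr mean return interval of the generic
#'   stand-destroying disturbance (years); `Inf` disables it.
#' @param hazard_baseline,hazard_slope,hazard_exp background hazard
#'   shape (`b0`, `b1`, `p` above).
#' @param establishment_density_m2 stem density of a newly established
#'   cohort (individuals per m2).
#' @param establishment_cai crown-area index below which new cohorts can
#'   establish.
#' @param establishment_min_gap_yr a PFT re-establishes on a patch only
#'   if it has no cohort younger than this (years).
#' @param self_thinning_cai crown-area index above which proportional
#'   self-thinning mortality brings cover back to the threshold.
#' @param crown_r0_m,crown_r_slope crown radius allometry
#'   `r = r0 + slope * D_cm` (m).
#' @param establishment_pfts PFT names allowed to establish; `NULL`
#'   means every PFT of the group.
#' @param prune_density_m2 cohorts thinner than this are dropped.
#' @return Object of class `demography_config`.
#' @export
demography_config <- function(disturbance_interval_yr = 150,
                              hazard_baseline = 0.2,
                              hazard_slope = 1.832,
                              hazard_exp = 4,
                              establishment_density_m2 = 0.005,
                              establishment_cai = 1.2,
                              establishment_min_gap_yr = 10,
                              self_thinning_cai = 3,
                              crown_r0_m = 0.5,
                              crown_r_slope = 0.09,
                              establishment_pfts = NULL,
                              prune_density_m2 = 1e-10) {
  stopifnot(disturbance_interval_yr > 0, hazard_baseline >= 0,
            hazard_slope >= 0, hazard_exp > 0,
            establishment_density_m2 >= 0, self_thinning_cai > 0)
  structure(as.list(environment()), class = "demography_config")
}

#' Annual background mortality probability
#'
#' Monotone non-decreasing in age; the hazard is scaled by PFT longevity
#' so that the mean age at death approximately equals `longevity_yr`.
#'
#' @param age_yr cohort age(s), years >= 0.
#' @param pft a [pft()] object.
#' @param cfg a [demography_config()].
#' @return annual death probability in `[0, 1)`.
#' @export
background_mortality_rate <- function(age_yr, pft, cfg = demography_config()) {
  stopifnot(all(age_yr >= 0))
  L <- pft$longevity_yr
  h <- (cfg$hazard_baseline + cfg$hazard_slope * (age_yr / L)^cfg$hazard_exp) / L
  1 - exp(-h)
}

#' Crown area per individual
#'
#' @param diameter_cm stem diameter(s), cm.
#' @param cfg a [demography_config()].
#' @return crown area in m2 (`pi * (r0 + slope * D)^2`).
#' @export
crown_area <- function(diameter_cm, cfg = demography_config()) {
  pi * (cfg$crown_r0_m + cfg$crown_r_slope * diameter_cm)^2
}

patch_cai <- function(p, cfg) {
  ch <- p$cohorts
  if (nrow(ch) == 0) return(0)
  sum(ch$density_m2 * crown_area(ch$diameter_cm, cfg))
}

# ---------------------------------------------------------------------------
# Mortality ledger
# ---------------------------------------------------------------------------

#' Create an empty mortality ledger
#'
#' The ledger books every killed stem exactly once under one cause
#' (lightning, background, disturbance, self_thinning; a fire slot is
#' kept for comparability but never filled here), split by size class.
#'
#' @return empty data frame with columns `year`, `cause`, `size_class`,
#'   `trees_killed`, `biomass_killed_kgC`.
#' @export
new_ledger <- function() {
  data.frame(year = integer(), cause = character(), size_class = character(),
             trees_killed = numeric(), biomass_killed_kgC = numeric(),
             stringsAsFactors = FALSE)
}

#' Append kill events to a ledger
#'
#' @param ledger a ledger from [new_ledger()].
#' @param year simulation year.
#' @param cause one of `lightning`, `background`, `disturbance`,
#'   `self_thinning`, `fire`.
#' @param size_class,trees,biomass parallel vectors of kill bookings.
#' @return the extended ledger.
#' @export
ledger_add <- function(ledger, year, cause, size_class, trees, biomass) {
  stopifnot(cause %in% mortality_causes, all(trees >= 0), all(biomass >= 0))
  keep <- trees > 0
  if (!any(keep)) return(ledger)
  rbind(ledger, data.frame(year = year, cause = cause,
                           size_class = as.character(size_class)[keep],
                           trees_killed = trees[keep],
                           biomass_killed_kgC = biomass[keep],
                           stringsAsFactors = FALSE))
}

#' Attribute mortality shares by cause
#'
#' @param ledger a non-empty mortality ledger.
#' @return list with `trees` (size class x cause matrix of percentage
#'   shares, rows summing to 100 where the class saw any death),
#'   `biomass` (named vector of percentage shares summing to 100) and
#'   `totals` (trees and biomass killed per cause).
#' @export
attribute <- function(ledger) {
  if (nrow(ledger) == 0) stop("empty ledger: nothing to attribute")
  classes <- size_class_names()
  tr <- tapply(ledger$trees_killed,
               list(factor(ledger$size_class, classes),
                    factor(ledger$cause, mortality_causes)), sum)
  tr[is.na(tr)] <- 0
  row_tot <- rowSums(tr)
  trees_pct <- tr
  nz <- row_tot > 0
  trees_pct[nz, ] <- 100 * tr[nz, , drop = FALSE] / row_tot[nz]
  bm <- tapply(ledger$biomass_killed_kgC,
               factor(ledger$cause, mortality_causes), sum)
  bm[is.na(bm)] <- 0
  biomass_pct <- if (sum(bm) > 0) 100 * bm / sum(bm) else bm
  list(trees = trees_pct, biomass = biomass_pct,
       totals = list(trees = colSums(tr), biomass_kgC = bm))
}

# ---------------------------------------------------------------------------
# Annual step
# ---------------------------------------------------------------------------

grow_cohorts <- function(ch, pfts) {
  if (nrow(ch) == 0) return(ch)
  g <- vapply(ch$pft, function(nm) pfts[[nm]]$growth_rate_cm_yr, numeric(1))
  dmax <- vapply(ch$pft, function(nm) pfts[[nm]]$d_max_cm, numeric(1))
  ch$diameter_cm <- ch$diameter_cm + pmax(0, g * (1 - ch$diameter_cm / dmax))
  ch$age_yr <- ch$age_yr + 1
  ch
}

#' Advance a patch group by one year
#'
#' Per member patch the order is: growth increment, background mortality,
#' self-thinning, generic stand-destroying disturbance (probability
#' `1 / interval`, kills every cohort); then lightning acts at group
#' level via [simulate_year()]; finally establishment adds new cohorts on
#' patches whose crown cover dropped below the threshold. All deaths are
#' booked in the ledger by cause and size class.
#'
#' @param group a [patch_group()].
#' @param year integer simulation year (ledger key).
#' @param demog a [demography_config()].
#' @param ledger a mortality ledger.
#' @param lightning `NULL` for a lightning-free year, else a list with
#'   `density_km2_yr`, `cfg` (a [lightning_config()]) and optionally
#'   `geom` (a [geometry_config()]).
#' @return list with `group`, `ledger` and `n_strikes`.
#' @export
step_year <- function(group, year, demog = demography_config(),
                      ledger = new_ledger(), lightning = NULL) {
  area <- group$patches[[1]]$area_m2
  allom <- group$allom
  p_dist <- 1 / demog$disturbance_interval_yr

  book <- function(ledger, cause, ch, frac) {
    trees <- ch$density_m2 * frac * area
    bio <- trees * biomass_per_individual(ch$diameter_cm, allom)
    cls <- as.character(classify_size(ch$diameter_cm))
    ledger_add(ledger, year, cause, cls, trees, bio)
  }

  for (i in seq_along(group$patches)) {
    p <- group$patches[[i]]
    ch <- grow_cohorts(p$cohorts, group$pfts)
    ch$height_m <- if (nrow(ch) > 0) tree_height(ch$diameter_cm, allom) else numeric()
    p$age_yr <- p$age_yr + 1

    if (nrow(ch) > 0) {
      # background mortality (expected-value thinning)
      q <- vapply(seq_len(nrow(ch)), function(j) {
        background_mortality_rate(ch$age_yr[j], group$pfts[[ch$pft[j]]], demog)
      }, numeric(1))
      ledger <- book(ledger, "background", ch, q)
      ch$density_m2 <- ch$density_m2 * (1 - q)

      # self-thinning back to the crown-cover ceiling
      cai <- sum(ch$density_m2 * crown_area(ch$diameter_cm, demog))
      if (cai > demog$self_thinning_cai) {
        f <- 1 - demog$self_thinning_cai / cai
        ledger <- book(ledger, "self_thinning", ch, f)
        ch$density_m2 <- ch$density_m2 * (1 - f)
      }
    }

    # generic stand-destroying disturbance
    if (is.finite(demog$disturbance_interval_yr) &&
        stats::runif(1) < p_dist) {
      if (nrow(ch) > 0) ledger <- book(ledger, "disturbance", ch, 1)
      ch <- ch[0, , drop = FALSE]
      p$age_yr <- 0
    }

    ch <- ch[ch$density_m2 > demog$prune_density_m2, , drop = FALSE]
    p$cohorts <- ch
    group$patches[[i]] <- p
  }

  # lightning at group level. The year's lightning runs on its own RNG
  # substream, seeded from the main stream: one integer is always drawn
  # (lightning enabled or not) and the main stream is restored
  # afterwards, so a run with all rates 0 is bit-for-bit identical to a
  # lightning-free run under the same seed.
  n_strikes <- rep(0L, length(group$patches))
  lightning_seed <- sample.int(.Machine$integer.max, 1)
  if (!is.null(lightning)) {
    geom <- if (is.null(lightning$geom)) geometry_config() else lightning$geom
    main_state <- .Random.seed
    set.seed(lightning_seed)
    res <- simulate_year(group, lightning$density_km2_yr, lightning$cfg, geom)
    assign(".Random.seed", main_state, envir = globalenv())
    group <- res$group
    n_strikes <- res$n_strikes
    if (nrow(res$kills) > 0) {
      ledger <- ledger_add(ledger, year, "lightning", res$kills$size_class,
                           res$kills$individuals, res$kills$biomass_kgC)
    }
  }

  # establishment on open patches
  est_pfts <- demog$establishment_pfts
  if (is.null(est_pfts)) est_pfts <- names(group$pfts)
  for (i in seq_along(group$patches)) {
    p <- group$patches[[i]]
    if (patch_cai(p, demog) >= demog$establishment_cai) next
    for (nm in est_pfts) {
      young <- p$cohorts$pft == nm & p$cohorts$age_yr < demog$establishment_min_gap_yr
      if (any(young)) next
      p$cohorts <- rbind(p$cohorts,
                         cohorts(nm, 0, 1, demog$establishment_density_m2,
                                 allom))
    }
    group$patches[[i]] <- p
  }

  list(group = group, ledger = ledger, n_strikes = n_strikes)
}

#' Run a multi-year stand simulation
#'
#' @param group starting [patch_group()].
#' @param years number of years to simulate.
#' @param demog a [demography_config()].
#' @param lightning `NULL` or the lightning argument of [step_year()].
#' @param seed optional RNG seed set before the run.
#' @return list with `group` (final state), `ledger`, `trajectory`
#'   (data frame: year, stems and biomass by size class, strikes) and
#'   `attribution` (from [attribute()], `NULL` if nothing died).
#' @export
run_stand_simulation <- function(group, years, demog = demography_config(),
                                 lightning = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ledger <- new_ledger()
  classes <- size_class_names()
  traj <- vector("list", years)
  for (y in seq_len(years)) {
    st <- step_year(group, y, demog, ledger, lightning)
    group <- st$group
    ledger <- st$ledger
    dens <- class_densities(group)
    tot <- group_totals(group)
    traj[[y]] <- data.frame(year = y, t(dens), stems = tot$stems,
                            biomass_kgC = tot$biomass_kgC,
                            strikes = sum(st$n_strikes))
  }
  traj <- do.call(rbind, traj)
  names(traj)[2:5] <- paste0("density_", classes)
  attribution <- if (nrow(ledger) > 0) attribute(ledger) else NULL
  list(group = group, ledger = ledger, trajectory = traj,
       attribution = attribution)
}

#' Write a ledger as per-hectare annual rates
#'
#' @param ledger a mortality ledger.
#' @param group the simulated [patch_group()] (for the reference area).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(ledger, group, path) {
  area_ha <- length(group$patches) * group$patches[[1]]$area_m2 / 1e4
  out <- ledger
  out$trees_killed_per_ha <- out$trees_killed / area_ha
  out$biomass_killed_kgC_per_ha <- out$biomass_killed_kgC / area_ha
  out$trees_killed <- NULL
  out$biomass_killed_kgC <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
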