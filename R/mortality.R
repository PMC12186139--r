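# ---------------------------------------------------------------------------
# Lightning kills on a patch group
# ---------------------------------------------------------------------------

#' Lightning mortality configuration
#'
#' @param rate_table a `mortality_rate_table` covering every size class
#'   and zone (from [estimate_rates()], [rate_table()] or
#'   [synthetic_rate_table()]).
#' @param stochastic_kills if `FALSE` (default), kills are expected
#'   values (fractional stems, matching continuous cohort densities); if
#'   `TRUE`, integer kills are drawn per (cohort, zone).
#' @param merge_factor expected number of patches per group; checked
#'   against the group at application time. `NULL` accepts any group.
#' @return Object of class `lightning_config`.
#' @export
lightning_config <- function(rate_table, stochastic_kills = FALSE,
                             merge_factor = NULL) {
  stopifnot(inherits(rate_table, "mortality_rate_table"))
  # every (class, zone) cell must be present
  rate_lookup(rate_table,
              rep(size_class_names(), times = length(zone_names())),
              rep(zone_names(), each = 4))
  structure(list(rate_table = rate_table,
                 stochastic_kills = isTRUE(stochastic_kills),
                 merge_factor = merge_factor),
            class = "lightning_config")
}

#' Effective mortality rate after PFT vulnerability scaling
#'
#' Empirical rates were measured in a tropical forest; extratropical
#' broadleaf and needleleaf PFTs multiply them by their vulnerability
#' factor, capped at 1.
#'
#' @param base_rate rate(s) in `[0, 1]`.
#' @param pft a [pft()] object (or a bare numeric multiplier).
#' @return rate(s) in `[0, 1]`.
#' @export
effective_rate <- function(base_rate, pft) {
  stopifnot(all(base_rate >= 0), all(base_rate <= 1))
  mult <- if (inherits(pft, "pft")) pft$lightning_vulnerability else pft
  pmin(base_rate * mult, 1)
}

empty_kill_events <- function() {
  data.frame(patch = integer(), pft = character(), size_class = character(),
             zone = character(), individuals = numeric(),
             biomass_kgC = numeric(), stringsAsFactors = FALSE)
}

# stochastic rounding of a continuous exposure to an integer stem count
integer_exposure <- function(x) {
  n <- floor(x)
  n + stats::rbinom(1, 1, x - n)
}

#' Apply one lightning strike to a patch group
#'
#' Implements the per-strike kill algorithm: (a) a strike landing inside
#' the patch disc hits one individual of the tallest cohort across all
#' member patches, which dies with the direct-hit rate of its size class
#' (times PFT vulnerability); (b) every cohort, treated as present on the
#' struck patch at `density / M` (merge factor `M`), loses stems in each
#' distance ring according to the ring area inside the patch and the
#' ring's mortality rate. Densities never drop below zero.
#'
#' @param group a [patch_group()].
#' @param strike one row from [sample_strike()].
#' @param cfg a [lightning_config()].
#' @param geom a [geometry_config()].
#' @return list with `group` (updated densities) and `kills` (one row per
#'   kill event: patch, pft, size_class, zone, individuals, biomass_kgC).
#' @export
apply_strike <- function(group, strike, cfg, geom = geometry_config()) {
  stopifnot(inherits(group, "patch_group"), inherits(cfg, "lightning_config"))
  if (!is.null(cfg$merge_factor) && merge_factor(group) != cfg$merge_factor) {
    stop("group size does not match the configured merge factor")
  }
  M <- merge_factor(group)
  area <- group$patches[[1]]$area_m2
  kills <- list()
  tab <- cfg$rate_table

  # all kills are evaluated against the standing population at strike
  # time, then subtracted jointly (capped at what the cohort holds)

  # (a) direct hit on the tallest cohort of the whole group
  tc <- if (isTRUE(strike$in_patch)) tallest_cohort(group) else NULL
  direct_dead <- 0
  if (!is.null(tc)) {
    cls <- as.character(classify_size(tc$cohort$diameter_cm))
    p <- effective_rate(rate_lookup(tab, cls, "direct"),
                        group$pfts[[tc$cohort$pft]])
    direct_dead <- if (cfg$stochastic_kills) stats::rbinom(1, 1, p) else p
  }

  # (b) ring kills for every cohort at merge-reduced density
  rings <- distance_zones(include_direct = FALSE)
  ring_areas <- vapply(seq_len(nrow(rings)), function(k) {
    zone_area_in_patch(strike$distance_m, rings[k, ], geom)
  }, numeric(1))
  for (i in seq_along(group$patches)) {
    ch <- group$patches[[i]]$cohorts
    if (nrow(ch) == 0) next
    for (j in seq_len(nrow(ch))) {
      if (ch$density_m2[j] <= 0) next
      cls <- as.character(classify_size(ch$diameter_cm[j]))
      eff <- effective_rate(rate_lookup(tab, cls, rings$name),
                            group$pfts[[ch$pft[j]]])
      exposed <- (ch$density_m2[j] / M) * ring_areas
      dead <- if (cfg$stochastic_kills) {
        vapply(seq_along(exposed), function(k) {
          stats::rbinom(1, integer_exposure(exposed[k]), eff[k])
        }, numeric(1))
      } else {
        exposed * eff
      }
      is_struck <- !is.null(tc) && tc$patch == i && tc$row == j
      total <- sum(dead) + if (is_struck) direct_dead else 0
      if (total <= 0) next
      avail <- ch$density_m2[j] * area
      scale <- if (total > avail) avail / total else 1
      dead <- dead * scale
      ch$density_m2[j] <- max(0, ch$density_m2[j] - total * scale / area)
      if (is_struck && direct_dead * scale > 0) {
        kills[[length(kills) + 1]] <- data.frame(
          patch = i, pft = ch$pft[j], size_class = cls, zone = "direct",
          individuals = direct_dead * scale,
          biomass_kgC = direct_dead * scale *
            biomass_per_individual(ch$diameter_cm[j], group$allom))
      }
      keep <- dead > 0
      if (any(keep)) {
        kills[[length(kills) + 1]] <- data.frame(
          patch = i, pft = ch$pft[j], size_class = cls,
          zone = rings$name[keep], individuals = dead[keep],
          biomass_kgC = dead[keep] * biomass_per_individual(ch$diameter_cm[j],
                                                            group$allom))
      }
    }
    group$patches[[i]]$cohorts <- ch
  }
  kills <- if (length(kills) == 0) empty_kill_events() else do.call(rbind, kills)
  list(group = group, kills = kills)
}

#' Simulate one year of lightning on a patch group
#'
#' Each member patch draws its own annual strike count from the binomial
#' strike-count model and samples its strike locations independently over
#' its extended disc; strikes are applied in sampled order.
#'
#' @param group a [patch_group()].
#' @param density_km2_yr cloud-to-ground flash density (flashes km-2 yr-1).
#' @param cfg a [lightning_config()].
#' @param geom a [geometry_config()].
#' @return list with `group`, `kills` (all kill events of the year) and
#'   `n_strikes` (strikes drawn per member patch).
#' @export
simulate_year <- function(group, density_km2_yr, cfg,
                          geom = geometry_config()) {
  n_patch <- length(group$patches)
  counts <- annual_strike_count(density_km2_yr, geom, n = n_patch)
  kills <- list()
  for (p in seq_len(n_patch)) {
    if (counts[p] == 0) next
    strikes <- sample_strike(geom, counts[p])
    for (s in seq_len(nrow(strikes))) {
      res <- apply_strike(group, strikes[s, ], cfg, geom)
      group <- res$group
      if (nrow(res$kills) > 0) kills[[length(kills) + 1]] <- res$kills
    }
  }
  kills <- if (length(kills) == 0) empty_kill_events() else do.call(rbind, kills)
  list(group = group, kills = kills, n_strikes = counts)
}

#' Deterministic per-strike kill expectation
#'
#' Integrates the ring-kill expression over the uniform strike-location
#' distribution on the extended disc (radial quadrature with density
#' `2 d / R_ext^2`) and adds the direct-hit term weighted by the
#' probability that a strike lands inside the patch. Evaluates stands
#' without Monte-Carlo noise.
#'
#' @param group a [patch_group()] (densities as given; not modified).
#' @param cfg a [lightning_config()].
#' @param geom a [geometry_config()].
#' @param n_quad number of radial quadrature nodes.
#' @return list with `total`, `per_size`, `ring_per_size`,
#'   `direct_per_size` (expected stems killed per strike).
#' @export
kills_per_strike_expectation <- function(group, cfg, geom = geometry_config(),
                                         n_quad = 2001) {
  M <- merge_factor(group)
  classes <- size_class_names()
  rings <- distance_zones(include_direct = FALSE)
  d <- seq(0, geom$extended_radius_m, length.out = n_quad)
  w <- 2 * d / geom$extended_radius_m^2   # radial pdf of a uniform disc

  # expected in-patch area of each ring over the strike distribution
  mean_area <- vapply(seq_len(nrow(rings)), function(k) {
    a <- zone_area_in_patch(d, rings[k, ], geom)
    pracma::trapz(d, a * w)
  }, numeric(1))

  ring <- stats::setNames(numeric(4), classes)
  for (p in group$patches) {
    ch <- p$cohorts
    if (nrow(ch) == 0) next
    for (j in seq_len(nrow(ch))) {
      if (ch$density_m2[j] <= 0) next
      cls <- as.character(classify_size(ch$diameter_cm[j]))
      eff <- effective_rate(rate_lookup(cfg$rate_table, cls, rings$name),
                            group$pfts[[ch$pft[j]]])
      ring[cls] <- ring[cls] + sum((ch$density_m2[j] / M) * mean_area * eff)
    }
  }

  direct <- stats::setNames(numeric(4), classes)
  tc <- tallest_cohort(group)
  if (!is.null(tc)) {
    cls <- as.character(classify_size(tc$cohort$diameter_cm))
    p_in <- geom$patch_area_m2 / geom$extended_area_m2
    direct[cls] <- p_in * effective_rate(
      rate_lookup(cfg$rate_table, cls, "direct"),
      group$pfts[[tc$cohort$pft]])
  }
  per_size <- ring + direct
  list(total = sum(per_size), per_size = per_size,
       ring_per_size = ring, direct_per_size = direct)
}

#' Size class of the cohort a strike would hit
#'
#' Convenience accessor for strike-size-distribution analyses (e.g. the
#' merge-factor sensitivity): the size class of the tallest cohort of a
#' group, or `NA` for an empty group.
#'
#' @param group a [patch_group()].
#' @return size class name or `NA_character_`.
#' @export
tallest_class <- function(group) {
  tc <- tallest_cohort(group)
  if (is.null(tc)) return(NA_character_)
  as.character(classify_size(tc$cohort$diameter_cm))
}

#' Split a patch group into smaller groups
#'
#' Partitions the member patches into consecutive groups of `m` patches
#' (sharing the PFT set and allometry), for merge-factor sensitivity
#' analyses: the same landscape evaluated at merge factors 1, 5, 10.
#'
#' @param group a [patch_group()] whose size is a multiple of `m`.
#' @param m target group size.
#' @return list of [patch_group()]s.
#' @export
split_group <- function(group, m) {
  n <- length(group$patches)
  if (n %% m != 0) stop("group size must be a multiple of m")
  lapply(split(seq_len(n), rep(seq_len(n / m), each = m)), function(idx) {
    patch_group(group$patches[idx], pfts = group$pfts, allom = group$allom)
  })
}

#' Distribution of strike-hit size classes across merge factors
#'
#' Generates replicate landscapes, partitions each into groups of the
#' requested merge factor, and tallies the size class of the cohort a
#' strike would hit (the tallest cohort) in every group. Larger merge
#' factors search taller cohorts over more patches, shifting hits
#' towards the largest class.
#'
#' @param merge_factor patches merged per group.
#' @param n_landscapes replicate landscapes to generate.
#' @param profile passed to [gen_stand()].
#' @param seed RNG seed for the first landscape (incremented per
#'   landscape).
#' @param landscape_patches patches per landscape; must be a multiple of
#'   `merge_factor`.
#' @return named vector of hit fractions per size class (plus `empty`
#'   for groups with no stems).
#' @export
strike_size_distribution <- function(merge_factor, n_landscapes = 100,
                                     profile = "bci_like", seed = 1,
                                     landscape_patches = 10) {
  hits <- character()
  for (k in seq_len(n_landscapes)) {
    land <- gen_stand(profile, seed = seed + k - 1,
                      n_patches = landscape_patches)
    for (g in split_group(land, merge_factor)) {
      cls <- tallest_class(g)
      hits <- c(hits, if (is.na(cls)) "empty" else cls)
    }
  }
  tab <- table(factor(hits, c(size_class_names(), "empty")))
  as.numeric(tab / sum(tab)) |> stats::setNames(names(tab))
}

#' Total stems and biomass of a patch group
#'
#' @param group a [patch_group()].
#' @return list with `stems` (individuals, summed over member patches)
#'   and `biomass_kgC`.
#' @export
group_totals <- function(group) {
  stems <- 0
  biomass <- 0
  for (p in group$patches) {
    ch <- p$cohorts
    if (nrow(ch) == 0) next
    stems <- stems + sum(ch$density_m2) * p$area_m2
    biomass <- biomass + sum(ch$density_m2 * p$area_m2 *
                               biomass_per_individual(ch$diameter_cm,
                                                      group$allom))
  }
  list(stems = stems, biomass_kgC = biomass)
}
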