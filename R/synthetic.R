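# ---------------------------------------------------------------------------
# Synthetic fixtures: stands, strike surveys, flash records
# ---------------------------------------------------------------------------

#' Synthetic mortality-rate table
#'
#' A made-up truth table shaped like field observations — rates increase
#' with tree size and fall off with distance from the strike — but with
#' arbitrary values. It is *synthetic*: it is not a set of measured
#' rates and is only meant to drive simulations and recovery tests.
#'
#' @return a `mortality_rate_table`.
#' @export
synthetic_rate_table <- function() {
  m <- rbind(
    tiny   = c(0.45, 0.040, 0.020, 0.010, 0.005, 0.002),
    small  = c(0.55, 0.080, 0.040, 0.020, 0.010, 0.005),
    medium = c(0.65, 0.140, 0.080, 0.040, 0.020, 0.010),
    large  = c(0.80, 0.220, 0.120, 0.070, 0.040, 0.020)
  )
  colnames(m) <- zone_names()
  rate_table(m)
}

class_diameter_range <- function(cls) {
  tab <- size_classes()
  i <- match(cls, tab$name)
  c(tab$lower_cm[i], min(tab$upper_cm[i], 100))
}

# invert the logistic growth curve to get a plausible cohort age
age_from_diameter <- function(d, p) {
  pmax(0, -p$d_max_cm / p$growth_rate_cm_yr * log(pmax(1e-9, 1 - d / p$d_max_cm)))
}

#' Generate a synthetic patch group
#'
#' Draws cohorts so that the group-mean stem density of each size class
#' (see [class_densities()]) equals the profile exactly. The `bci_like`
#' profile uses tropical-forest densities of 0 tiny, 0.006 small, 0.012
#' medium and 0.004 large stems per m2. Classes occupy only a subset of
#' the member patches (large trees roughly half of them), emulating the
#' limited within-patch heterogeneity of cohort models that motivates
#' merging patches for the tallest-cohort search.
#'
#' @param profile `"bci_like"`, `"temperate_conifer"` or `"uniform"`.
#' @param seed RNG seed (the generator is a pure function of profile,
#'   seed and the shape arguments).
#' @param n_patches patches per group (merge factor), default 5.
#' @param uniform_density per-class density for the `uniform` profile;
#'   0 yields an empty group.
#' @param pfts,allom passed to [patch_group()].
#' @return a [patch_group()].
#' @export
gen_stand <- function(profile = c("bci_like", "temperate_conifer", "uniform"),
                      seed = 1, n_patches = 5, uniform_density = 0.005,
                      pfts = default_pfts(), allom = allometry_params()) {
  profile <- match.arg(profile)
  set.seed(seed)
  classes <- size_class_names()
  target <- switch(profile,
    bci_like = c(tiny = 0, small = 0.006, medium = 0.012, large = 0.004),
    temperate_conifer = c(tiny = 0.002, small = 0.004, medium = 0.008,
                          large = 0.002),
    uniform = stats::setNames(rep(uniform_density, 4), classes)
  )
  pft_name <- if (profile == "temperate_conifer") "NE" else "TrBE"
  occupancy <- c(tiny = 0.6, small = 0.8, medium = 0.9, large = 0.2)

  patch_cohorts <- replicate(n_patches, NULL, simplify = FALSE)
  for (cls in classes) {
    t_cls <- target[[cls]]
    if (t_cls <= 0) next
    n_occ <- max(1, round(occupancy[[cls]] * n_patches))
    occ <- sample(n_patches, n_occ)
    w <- stats::runif(n_occ, 0.5, 1.5)
    dens <- (t_cls * n_patches) * w / sum(w)   # sums to t_cls * M exactly
    rng <- class_diameter_range(cls)
    for (k in seq_along(occ)) {
      d <- stats::runif(1, rng[1], rng[2])
      patch_cohorts[[occ[k]]] <- rbind(
        patch_cohorts[[occ[k]]],
        cohorts(pft_name, round(age_from_diameter(d, pfts[[pft_name]])),
                d, dens[k], allom))
    }
  }
  patches <- lapply(patch_cohorts, function(ch) {
    if (is.null(ch)) ch <- cohorts()
    patch(ch)
  })
  patch_group(patches, pfts = pfts, allom = allom)
}

annulus_area_m2 <- function() {
  z <- distance_zones(include_direct = FALSE)
  stats::setNames(pi * (z$outer_m^2 - z$inner_m^2), z$name)
}

#' Generate a synthetic strike survey with known true rates
#'
#' The inverse of [estimate_rates()]: per strike, living tree counts per
#' (size class, zone) are drawn Poisson around a stand profile times the
#' annulus area, deaths are Bernoulli with the true rate, and each strike
#' carries one directly struck tree whose death follows the direct rate.
#' A fraction of records deliberately fails the estimation filters
#' (outside the plot, ambiguous location, or surveyed too early) to
#' exercise the scoping rules.
#'
#' @param truth list with `rate_table` (a `mortality_rate_table`) and
#'   optionally `stand_densities` (named per-class stems per m2).
#' @param n_strikes number of strikes, >= 1.
#' @param seed RNG seed.
#' @param min_days qualifying-survey threshold used when laying out
#'   survey days (records meant to qualify get a day >= this).
#' @param frac_failing fraction of strikes that fail the neighbour-scope
#'   filters.
#' @return list with `survey` and `census` data frames (the formats of
#'   [read_strike_survey_csv()] / [read_census_csv()]) and `truth`.
#' @export
gen_strike_survey <- function(truth = list(rate_table = synthetic_rate_table()),
                              n_strikes = 50, seed = 1, min_days = 346,
                              frac_failing = 0.2) {
  stopifnot(n_strikes >= 1)
  set.seed(seed)
  tab <- truth$rate_table
  dens <- truth$stand_densities
  if (is.null(dens)) {
    dens <- c(tiny = 0.020, small = 0.010, medium = 0.006, large = 0.003)
  }
  classes <- size_class_names()
  rings <- zone_names(include_direct = FALSE)
  ring_area <- annulus_area_m2()

  survey <- list()
  census <- list()
  tree_counter <- 0
  for (s in seq_len(n_strikes)) {
    sid <- sprintf("S%03d", s)
    failing <- stats::runif(1) < frac_failing
    fail_mode <- if (failing) sample(c("out_plot", "ambiguous", "early"), 1) else "none"
    in_plot <- fail_mode != "out_plot"
    unambiguous <- fail_mode != "ambiguous"
    day <- if (fail_mode == "early") {
      sample(30:(min_days - 1), 1)
    } else {
      sample(min_days:(min_days + 200), 1)
    }

    rows <- list()
    # one directly struck tree per strike
    cls_d <- sample(classes, 1, prob = c(0.05, 0.15, 0.30, 0.50))
    rng <- class_diameter_range(cls_d)
    tree_counter <- tree_counter + 1
    rows[[1]] <- data.frame(
      strike_id = sid, in_plot = in_plot, location_unambiguous = unambiguous,
      survey_day = day, tree_id = sprintf("T%05d", tree_counter),
      diameter_cm = stats::runif(1, rng[1], rng[2]), zone = "direct",
      directly_struck = TRUE,
      died = stats::runif(1) < rate_lookup(tab, cls_d, "direct"))

    for (cls in classes) {
      for (z in rings) {
        living <- stats::rpois(1, dens[[cls]] * ring_area[[z]])
        census[[length(census) + 1]] <- data.frame(
          strike_id = sid, size_class = cls, zone = z, living_count = living)
        if (living == 0) next
        killed <- stats::rbinom(1, living, rate_lookup(tab, cls, z))
        if (killed == 0) next
        rng <- class_diameter_range(cls)
        tree_ids <- sprintf("T%05d", tree_counter + seq_len(killed))
        tree_counter <- tree_counter + killed
        rows[[length(rows) + 1]] <- data.frame(
          strike_id = sid, in_plot = in_plot,
          location_unambiguous = unambiguous, survey_day = day,
          tree_id = tree_ids,
          diameter_cm = stats::runif(killed, rng[1], rng[2]), zone = z,
          directly_struck = FALSE, died = TRUE)
      }
    }
    survey[[s]] <- do.call(rbind, rows)
  }
  list(survey = do.call(rbind, survey), census = do.call(rbind, census),
       truth = list(rate_table = tab, stand_densities = dens, seed = seed))
}

#' Generate synthetic labelled flash records
#'
#' Per-cell flash counts are Poisson with mean
#' `intensity x cell area x years`, placed uniformly within the cell and
#' over the period, and labelled CG with probability `cg_fraction`.
#'
#' @param intensity_grid a [density_grid()] holding total-lightning
#'   intensity (flashes km-2 yr-1).
#' @param years period length (years), >= 1.
#' @param seed RNG seed.
#' @param cg_fraction probability that a flash reaches the ground.
#' @param start start date of the period.
#' @return data frame with `timestamp`, `lat`, `lon`, `type`.
#' @export
gen_flash_records <- function(intensity_grid, years = 1, seed = 1,
                              cg_fraction = 0.75, start = "2016-01-01") {
  stopifnot(years >= 1, cg_fraction >= 0, cg_fraction <= 1)
  set.seed(seed)
  g <- intensity_grid
  half <- g$resolution_deg / 2
  start <- as.Date(start)
  n_days <- round(years * 365.25)
  out <- list()
  for (i in seq_along(g$lat)) {
    area <- cell_area_km2(g$lat[i], g$resolution_deg)
    for (j in seq_along(g$lon)) {
      n <- stats::rpois(1, g$density[i, j] * area * years)
      if (n == 0) next
      out[[length(out) + 1]] <- data.frame(
        timestamp = as.character(start + sample.int(n_days, n, replace = TRUE) - 1),
        lat = stats::runif(n, g$lat[i] - half, g$lat[i] + half),
        lon = stats::runif(n, g$lon[j] - half, g$lon[j] + half),
        type = ifelse(stats::runif(n) < cg_fraction, "CG", "IC"))
    }
  }
  if (length(out) == 0) {
    return(data.frame(timestamp = character(), lat = numeric(),
                      lon = numeric(), type = character()))
  }
  do.call(rbind, out)
}
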