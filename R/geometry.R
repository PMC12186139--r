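# ---------------------------------------------------------------------------
# Strike target geometry
# ---------------------------------------------------------------------------

#' Strike-target geometry configuration
#'
#' The patch is modelled as a disc of the same area. Because flashover can
#' kill trees up to `reach_m` beyond the patch edge, strikes are sampled
#' over an extended disc of radius `patch_radius + reach`: for the default
#' 1000 m2 patch and 45 m reach the target area grows from 1000 to about
#' 12,406 m2.
#'
#' @param patch_area_m2 patch area (m2), > 0.
#' @param reach_m flashover reach beyond the patch edge (m), >= 0.
#' @param n_trials number of Bernoulli trials per year in the binomial
#'   strike-count model (default 365, i.e. daily trials).
#' @return Object of class `geometry_config` with derived fields
#'   `patch_radius_m`, `extended_radius_m`, `extended_area_m2`.
#' @export
geometry_config <- function(patch_area_m2 = 1000, reach_m = 45,
                            n_trials = 365) {
  if (patch_area_m2 <= 0) stop("patch_area_m2 must be positive")
  if (reach_m < 0) stop("reach_m must be non-negative")
  stopifnot(n_trials >= 1)
  r_p <- sqrt(patch_area_m2 / pi)
  structure(
    list(patch_area_m2 = patch_area_m2, reach_m = reach_m,
         n_trials = as.integer(n_trials),
         patch_radius_m = r_p,
         extended_radius_m = r_p + reach_m,
         extended_area_m2 = pi * (r_p + reach_m)^2),
    class = "geometry_config"
  )
}

#' Radius of the extended strike-target disc
#'
#' @param patch_area_m2 patch area (m2), > 0.
#' @param reach_m flashover reach (m), >= 0.
#' @return `sqrt(patch_area_m2 / pi) + reach_m`, in metres.
#' @examples
#' extended_radius(1000, 45) # ~62.8 m
#' @export
extended_radius <- function(patch_area_m2, reach_m) {
  if (any(patch_area_m2 <= 0)) stop("patch_area_m2 must be positive")
  if (any(reach_m < 0)) stop("reach_m must be non-negative")
  sqrt(patch_area_m2 / pi) + reach_m
}

#' Area of the extended strike-target disc
#'
#' @inheritParams extended_radius
#' @return area in m2.
#' @examples
#' extended_area(1000, 45) # ~12,406 m2
#' @export
extended_area <- function(patch_area_m2, reach_m) {
  pi * extended_radius(patch_area_m2, reach_m)^2
}

# ---------------------------------------------------------------------------
# Annual strike counts
# ---------------------------------------------------------------------------

#' Expected annual strikes on the extended disc
#'
#' @param density_km2_yr cloud-to-ground flash density (flashes km-2 yr-1).
#' @param cfg a [geometry_config()].
#' @return expected strikes per year (dimensionless).
#' @export
expected_annual_strikes <- function(density_km2_yr, cfg = geometry_config()) {
  stopifnot(density_km2_yr >= 0)
  density_km2_yr * cfg$extended_area_m2 / 1e6
}

#' Probability of at least one strike in a year
#'
#' Under the daily-trial binomial model, `1 - (1 - lambda/n)^n` with
#' `lambda` the expected annual strike count; under the Poisson model,
#' `1 - exp(-lambda)`. The two agree closely for realistic densities.
#'
#' @inheritParams expected_annual_strikes
#' @param method "binomial" (daily Bernoulli trials) or "poisson".
#' @return probability in `[0, 1]`.
#' @export
prob_strike_ge1 <- function(density_km2_yr, cfg = geometry_config(),
                            method = c("binomial", "poisson")) {
  method <- match.arg(method)
  lambda <- expected_annual_strikes(density_km2_yr, cfg)
  if (method == "poisson") return(1 - exp(-lambda))
  n <- cfg$n_trials
  p <- lambda / n
  if (p > 1) stop("per-trial probability exceeds 1; increase n_trials")
  1 - (1 - p)^n
}

#' Draw the number of strikes hitting the extended disc in one year
#'
#' The annual count is Binomial(`n_trials`, `lambda / n_trials`) with
#' `lambda` the expected annual strike count, i.e. one Bernoulli trial per
#' day by default. A Poisson alternative is provided; at realistic flash
#' densities the two are indistinguishable.
#'
#' @inheritParams prob_strike_ge1
#' @param n number of independent annual draws.
#' @return integer vector of length `n`.
#' @export
annual_strike_count <- function(density_km2_yr, cfg = geometry_config(),
                                method = c("binomial", "poisson"), n = 1) {
  method <- match.arg(method)
  lambda <- expected_annual_strikes(density_km2_yr, cfg)
  if (method == "poisson") return(stats::rpois(n, lambda))
  p <- lambda / cfg$n_trials
  if (p > 1) stop("per-trial probability exceeds 1; increase n_trials")
  stats::rbinom(n, cfg$n_trials, p)
}

# ---------------------------------------------------------------------------
# Strike placement
# ---------------------------------------------------------------------------

#' Sample strike locations uniformly over the extended disc
#'
#' Strike locations are uniform over the extended target disc, so the
#' radial distance from the patch centre has density `2 d / R_ext^2`:
#' most strikes land far from the centre, and only a fraction
#' `patch_area / extended_area` (~8% at defaults) inside the patch itself.
#'
#' @param cfg a [geometry_config()].
#' @param n number of strikes to sample.
#' @return data frame of class `strike` rows: `distance_m`, `angle_rad`,
#'   `in_patch`.
#' @export
sample_strike <- function(cfg = geometry_config(), n = 1) {
  d <- cfg$extended_radius_m * sqrt(stats::runif(n))
  data.frame(distance_m = d,
             angle_rad = stats::runif(n, 0, 2 * pi),
             in_patch = d <= cfg$patch_radius_m)
}

# ---------------------------------------------------------------------------
# Circle intersection areas
# ---------------------------------------------------------------------------

#' Intersection area of two discs
#'
#' Area of overlap between a disc of radius `R` and a disc of radius `r`
#' whose centres are `d` apart (the circular "lens"). Equals the smaller
#' disc when one contains the other and 0 when they are disjoint.
#'
#' @param R,r disc radii (m), >= 0.
#' @param d centre distance (m), >= 0. Vectorised over `d`.
#' @return area in m2.
#' @export
lens_area <- function(R, r, d) {
  stopifnot(R >= 0, r >= 0, all(d >= 0))
  out <- numeric(length(d))
  lo <- abs(R - r)
  hi <- R + r
  contained <- d <= lo
  disjoint <- d >= hi
  out[contained] <- pi * min(R, r)^2
  mid <- !contained & !disjoint
  if (any(mid)) {
    dm <- d[mid]
    # standard two-segment decomposition; clamp acos args for roundoff
    a1 <- (dm^2 + R^2 - r^2) / (2 * dm * R)
    a2 <- (dm^2 + r^2 - R^2) / (2 * dm * r)
    a1 <- pmin(pmax(a1, -1), 1)
    a2 <- pmin(pmax(a2, -1), 1)
    out[mid] <- R^2 * acos(a1) + r^2 * acos(a2) -
      0.5 * sqrt(pmax(0, (-dm + R + r) * (dm + R - r) * (dm - R + r) * (dm + R + r)))
  }
  out
}

#' Area of a distance zone lying inside the patch
#'
#' For a strike a distance `d` from the patch centre, the part of the ring
#' `inner < rho <= outer` around the strike that falls inside the patch
#' disc: `lens(R_p, outer, d) - lens(R_p, inner, d)`. Multiplying this
#' area by a cohort's (merge-reduced) density gives the number of stems of
#' that cohort exposed to the zone's mortality rate.
#'
#' @param strike one row from [sample_strike()], or a numeric distance
#'   from the patch centre (m).
#' @param zone zone name (one of `zone_names()` except `direct`) or a row
#'   of [distance_zones()].
#' @param cfg a [geometry_config()].
#' @return area in m2.
#' @export
zone_area_in_patch <- function(strike, zone, cfg = geometry_config()) {
  d <- if (is.numeric(strike)) strike else strike$distance_m
  if (is.character(zone)) {
    zt <- distance_zones()
    zone <- zt[zt$name == zone, , drop = FALSE]
    if (nrow(zone) == 0) stop("unknown zone")
  }
  if (is.na(zone$inner_m)) {
    stop("the direct zone has no ring area; direct hits use the direct-hit path")
  }
  lens_area(cfg$patch_radius_m, zone$outer_m, d) -
    lens_area(cfg$patch_radius_m, zone$inner_m, d)
}
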