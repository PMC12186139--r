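# ---------------------------------------------------------------------------
# Size classes and distance zones
# ---------------------------------------------------------------------------

#' Diameter size classes
#'
#' The four diameter classes used throughout: tiny (1-10 cm), small
#' (10-30 cm), medium (30-60 cm) and large (> 60 cm). Intervals are
#' half-open and lower-inclusive, so the boundary diameters 10, 30 and
#' 60 cm belong to the upper class.
#'
#' @return A data frame with columns `name`, `lower_cm`, `upper_cm`.
#' @export
size_classes <- function() {
  data.frame(
    name     = c("tiny", "small", "medium", "large"),
    lower_cm = c(1, 10, 30, 60),
    upper_cm = c(10, 30, 60, Inf),
    stringsAsFactors = FALSE
  )
}

#' @rdname size_classes
#' @export
size_class_names <- function() size_classes()$name

#' Classify stem diameters into size classes
#'
#' @param diameter_cm numeric vector of stem diameters in cm; all values
#'   must be >= 1 cm (the census threshold).
#' @return A factor with levels `tiny`, `small`, `medium`, `large`.
#' @examples
#' classify_size(c(5, 10, 29.999, 60))
#' @export
classify_size <- function(diameter_cm) {
  if (!is.numeric(diameter_cm)) stop("diameter_cm must be numeric")
  if (any(is.na(diameter_cm))) stop("diameter_cm contains NA")
  if (any(diameter_cm < 1)) {
    stop("diameter below the 1 cm census threshold is out of domain")
  }
  cls <- size_classes()
  idx <- findInterval(diameter_cm, cls$lower_cm)
  factor(cls$name[idx], levels = cls$name)
}

#' Distance zones around a strike location
#'
#' The neighbourhood of a struck tree is divided into five concentric
#' rings out to the 45 m flashover reach, plus the `direct` category for
#' the struck tree itself.
#'
#' @param include_direct logical; include the `direct` row (with NA radii)?
#' @return A data frame with columns `name`, `inner_m`, `outer_m`.
#' @export
distance_zones <- function(include_direct = TRUE) {
  z <- data.frame(
    name    = c("direct", "z0_10", "z10_20", "z20_30", "z30_40", "z40_45"),
    inner_m = c(NA, 0, 10, 20, 30, 40),
    outer_m = c(NA, 10, 20, 30, 40, 45),
    stringsAsFactors = FALSE
  )
  if (include_direct) z else z[z$name != "direct", ]
}

#' @rdname distance_zones
#' @export
zone_names <- function(include_direct = TRUE) distance_zones(include_direct)$name

# ---------------------------------------------------------------------------
# Plant functional types
# ---------------------------------------------------------------------------

#' Default lightning vulnerability multiplier
#'
#' Tropical PFTs carry the baseline vulnerability of 1.0 because the
#' empirical mortality rates come from a tropical forest. Extratropical
#' broadleaves are assumed 50% more vulnerable and needleleaves 80% more
#' vulnerable, reflecting their higher electrical resistance.
#'
#' @param leaf_habit "broadleaf" or "needleleaf"
#' @param tropical logical
#' @return dimensionless multiplier >= 1
#' @export
default_vulnerability <- function(leaf_habit, tropical) {
  leaf_habit <- match.arg(leaf_habit, c("broadleaf", "needleleaf"))
  if (leaf_habit == "needleleaf") 1.8 else if (tropical) 1.0 else 1.5
}

#' Construct a plant functional type
#'
#' @param name PFT name.
#' @param leaf_habit "broadleaf" or "needleleaf".
#' @param tropical logical flag.
#' @param lightning_vulnerability multiplier >= 1 applied to empirical
#'   mortality rates; defaults per [default_vulnerability()].
#' @param longevity_yr expected lifespan (years) used by background mortality.
#' @param d_max_cm asymptotic stem diameter (cm) for the growth curve.
#' @param growth_rate_cm_yr initial diameter increment (cm/yr).
#' @return An object of class `pft`.
#' @export
pft <- function(name, leaf_habit = "broadleaf", tropical = TRUE,
                lightning_vulnerability = NULL,
                longevity_yr = 350, d_max_cm = 120,
                growth_rate_cm_yr = 0.6) {
  leaf_habit <- match.arg(leaf_habit, c("broadleaf", "needleleaf"))
  if (is.null(lightning_vulnerability)) {
    lightning_vulnerability <- default_vulnerability(leaf_habit, tropical)
  }
  stopifnot(lightning_vulnerability >= 1, longevity_yr > 0, d_max_cm > 1,
            growth_rate_cm_yr > 0)
  structure(
    list(name = name, leaf_habit = leaf_habit, tropical = tropical,
         lightning_vulnerability = lightning_vulnerability,
         longevity_yr = longevity_yr, d_max_cm = d_max_cm,
         growth_rate_cm_yr = growth_rate_cm_yr),
    class = "pft"
  )
}

#' @export
print.pft <- function(x, ...) {
  cat(sprintf("<pft> %s (%s%s), vulnerability x%.2f, longevity %d yr\n",
              x$name, if (x$tropical) "tropical " else "", x$leaf_habit,
              x$lightning_vulnerability, round(x$longevity_yr)))
  invisible(x)
}

#' Built-in PFT set
#'
#' A minimal set of three PFTs spanning the vulnerability classes:
#' tropical broadleaf (x1.0), temperate broadleaf (x1.5) and
#' needleleaf conifer (x1.8).
#'
#' @return Named list of `pft` objects.
#' @export
default_pfts <- function() {
  list(
    TrBE = pft("TrBE", "broadleaf", tropical = TRUE,
               longevity_yr = 350, d_max_cm = 120, growth_rate_cm_yr = 0.6),
    TeBS = pft("TeBS", "broadleaf", tropical = FALSE,
               longevity_yr = 300, d_max_cm = 100, growth_rate_cm_yr = 0.5),
    NE   = pft("NE", "needleleaf", tropical = FALSE,
               longevity_yr = 400, d_max_cm = 90, growth_rate_cm_yr = 0.45)
  )
}

# ---------------------------------------------------------------------------
# Allometry
# ---------------------------------------------------------------------------

#' Power-law allometry parameters
#'
#' Heights only need to rank cohorts for the tallest-cohort rule, and
#' biomass only needs to scale killed stems into killed carbon, so both
#' are simple power laws of diameter: `kgC = biomass_coeff * D^biomass_exp`
#' and `m = height_coeff * D^height_exp`.
#'
#' @param biomass_coeff,biomass_exp biomass power law (kgC from D in cm).
#' @param height_coeff,height_exp height power law (m from D in cm).
#' @return Object of class `allometry_params`.
#' @export
allometry_params <- function(biomass_coeff = 0.06, biomass_exp = 2.5,
                             height_coeff = 1.3, height_exp = 0.75) {
  stopifnot(biomass_coeff > 0, biomass_exp > 0, height_coeff > 0,
            height_exp > 0)
  structure(list(biomass_coeff = biomass_coeff, biomass_exp = biomass_exp,
                 height_coeff = height_coeff, height_exp = height_exp),
            class = "allometry_params")
}

#' Aboveground carbon per individual
#'
#' @param diameter_cm stem diameter(s), cm, >= 1.
#' @param params an [allometry_params()] object.
#' @return kgC per individual.
#' @export
biomass_per_individual <- function(diameter_cm, params = allometry_params()) {
  stopifnot(all(diameter_cm >= 1))
  params$biomass_coeff * diameter_cm^params$biomass_exp
}

#' Tree height from diameter
#'
#' @inheritParams biomass_per_individual
#' @return height in m.
#' @export
tree_height <- function(diameter_cm, params = allometry_params()) {
  stopifnot(all(diameter_cm >= 1))
  params$height_coeff * diameter_cm^params$height_exp
}

# ---------------------------------------------------------------------------
# Cohorts, patches, patch groups
# ---------------------------------------------------------------------------

cohort_columns <- c("pft", "age_yr", "diameter_cm", "density_m2", "height_m")

#' Build a cohort table
#'
#' Cohorts are rows of a data frame: a PFT name, an age, a shared stem
#' diameter, and a continuous stem density (individuals per m2 of patch).
#'
#' @param pft character vector of PFT names.
#' @param age_yr,diameter_cm,density_m2 numeric vectors, recycled.
#' @param allom allometry used to derive heights.
#' @return data frame with the cohort columns.
#' @export
cohorts <- function(pft = character(), age_yr = numeric(),
                    diameter_cm = numeric(), density_m2 = numeric(),
                    allom = allometry_params()) {
  df <- data.frame(pft = as.character(pft), age_yr = age_yr,
                   diameter_cm = diameter_cm, density_m2 = density_m2,
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    stopifnot(all(df$density_m2 >= 0), all(df$diameter_cm >= 1))
    df$height_m <- tree_height(df$diameter_cm, allom)
  } else {
    df$height_m <- numeric()
  }
  df
}

#' Construct a patch
#'
#' @param cohorts cohort data frame as from [cohorts()]; may be empty.
#' @param area_m2 patch area, m2.
#' @param age_yr years since the last stand-destroying disturbance.
#' @return Object of class `patch`.
#' @export
patch <- function(cohorts = strikesim::cohorts(), area_m2 = 1000, age_yr = 0) {
  stopifnot(area_m2 > 0)
  missing_cols <- setdiff(cohort_columns, names(cohorts))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  structure(list(cohorts = cohorts, area_m2 = area_m2, age_yr = age_yr),
            class = "patch")
}

#' Construct a patch group
#'
#' A group of `M` replicate patches merged for the lightning mortality
#' calculation: every strike searches the tallest cohort across all
#' member patches, and ring kills act on densities divided by `M`.
#'
#' @param patches list of [patch()] objects sharing one area.
#' @param pfts named list of [pft()] objects covering every cohort PFT.
#' @param allom allometry shared by the group.
#' @return Object of class `patch_group`.
#' @export
patch_group <- function(patches, pfts = default_pfts(),
                        allom = allometry_params()) {
  stopifnot(length(patches) >= 1)
  stopifnot(all(vapply(patches, inherits, logical(1), "patch")))
  areas <- vapply(patches, function(p) p$area_m2, numeric(1))
  if (length(unique(areas)) != 1) stop("all patches in a group must share area")
  used <- unique(unlist(lapply(patches, function(p) p$cohorts$pft)))
  unknown <- setdiff(used, names(pfts))
  if (length(unknown) > 0) {
    stop("cohorts reference unknown PFTs: ", paste(unknown, collapse = ", "))
  }
  structure(list(patches = patches, pfts = pfts, allom = allom),
            class = "patch_group")
}

#' @export
print.patch_group <- function(x, ...) {
  n_coh <- sum(vapply(x$patches, function(p) nrow(p$cohorts), integer(1)))
  cat(sprintf("<patch_group> %d patches x %.0f m2, %d cohorts\n",
              length(x$patches), x$patches[[1]]$area_m2, n_coh))
  invisible(x)
}

#' Merge factor of a group
#' @param group a [patch_group()].
#' @export
merge_factor <- function(group) length(group$patches)

#' Find the tallest cohort across a patch group
#'
#' Returns the cohort with maximal height among all cohorts with positive
#' density across all member patches; lightning preferentially strikes
#' this cohort. Ties are broken by larger diameter, then by earlier
#' (patch, cohort) index, so results are reproducible.
#'
#' @param group a [patch_group()].
#' @return `NULL` if the group holds no woody individuals, otherwise a
#'   list with `patch` (index), `row` (cohort row index) and `cohort`
#'   (the one-row cohort data frame).
#' @export
tallest_cohort <- function(group) {
  best <- NULL
  for (i in seq_along(group$patches)) {
    ch <- group$patches[[i]]$cohorts
    if (nrow(ch) == 0) next
    for (j in seq_len(nrow(ch))) {
      if (ch$density_m2[j] <= 0) next
      cand <- c(ch$height_m[j], ch$diameter_cm[j])
      if (is.null(best) ||
          cand[1] > best$key[1] ||
          (cand[1] == best$key[1] && cand[2] > best$key[2])) {
        best <- list(patch = i, row = j, cohort = ch[j, , drop = FALSE],
                     key = cand)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$key <- NULL
  best
}

#' Stem density per size class
#'
#' Group-mean density (individuals per m2 of ground, i.e. the sum of
#' member-patch densities divided by the merge factor) per size class.
#'
#' @param group a [patch_group()].
#' @return named numeric vector over the four size classes.
#' @export
class_densities <- function(group) {
  out <- stats::setNames(numeric(4), size_class_names())
  M <- merge_factor(group)
  for (p in group$patches) {
    ch <- p$cohorts
    if (nrow(ch) == 0) next
    cls <- as.character(classify_size(ch$diameter_cm))
    for (k in seq_len(nrow(ch))) out[cls[k]] <- out[cls[k]] + ch$density_m2[k] / M
  }
  out
}

# ---------------------------------------------------------------------------
# File interfaces
# ---------------------------------------------------------------------------

#' Read a stand description CSV into a patch group
#'
#' Expected columns: `patch_id`, `pft`, `age_yr`, `diameter_cm`,
#' `density_per_m2`.
#'
#' @param path CSV file path.
#' @param pfts named list of [pft()] objects.
#' @param area_m2 patch area.
#' @param allom allometry parameters.
#' @return A [patch_group()].
#' @export
read_stand_csv <- function(path, pfts = default_pfts(), area_m2 = 1000,
                           allom = allometry_params()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patch_id", "pft", "age_yr", "diameter_cm", "density_per_m2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("stand CSV is missing columns: ", paste(miss, collapse = ", "))
  }
  ids <- sort(unique(df$patch_id))
  patches <- lapply(ids, function(id) {
    rows <- df[df$patch_id == id, , drop = FALSE]
    patch(cohorts(rows$pft, rows$age_yr, rows$diameter_cm,
                  rows$density_per_m2, allom), area_m2 = area_m2)
  })
  patch_group(patches, pfts = pfts, allom = allom)
}

#' Write a patch group to a stand description CSV
#'
#' @param group a [patch_group()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stand_csv <- function(group, path) {
  rows <- do.call(rbind, lapply(seq_along(group$patches), function(i) {
    ch <- group$patches[[i]]$cohorts
    if (nrow(ch) == 0) return(NULL)
    data.frame(patch_id = i, pft = ch$pft, age_yr = ch$age_yr,
               diameter_cm = ch$diameter_cm, density_per_m2 = ch$density_m2)
  }))
  if (is.null(rows)) {
    rows <- data.frame(patch_id = integer(), pft = character(),
                       age_yr = numeric(), diameter_cm = numeric(),
                       density_per_m2 = numeric())
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a PFT parameter CSV
#'
#' Expected columns: `name`, `leaf_habit`, `tropical`,
#' `lightning_vulnerability`, `longevity_yr`, `d_max_cm`; an optional
#' `growth_rate_cm_yr` column is honoured.
#'
#' @param path CSV file path.
#' @return Named list of [pft()] objects.
#' @export
read_pft_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "leaf_habit", "tropical", "lightning_vulnerability",
            "longevity_yr", "d_max_cm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("PFT CSV is missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(df$growth_rate_cm_yr)) df$growth_rate_cm_yr <- 0.6
  out <- lapply(seq_len(nrow(df)), function(i) {
    pft(df$name[i], df$leaf_habit[i], as.logical(df$tropical[i]),
        df$lightning_vulnerability[i], df$longevity_yr[i], df$d_max_cm[i],
        df$growth_rate_cm_yr[i])
  })
  stats::setNames(out, df$name)
}
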