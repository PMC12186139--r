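# ---------------------------------------------------------------------------
# Empirical mortality-rate estimation from strike surveys
# ---------------------------------------------------------------------------

#' Estimation configuration
#'
#' @param min_days minimum days between strike and survey for the survey
#'   to count (default 346, roughly one wet-season-to-wet-season year,
#'   long enough for most lightning-caused deaths to have occurred).
#' @return Object of class `estimation_config`.
#' @export
estimation_config <- function(min_days = 346) {
  stopifnot(min_days > 0)
  structure(list(min_days = min_days), class = "estimation_config")
}

validate_survey <- function(survey) {
  need <- c("strike_id", "in_plot", "location_unambiguous", "survey_day",
            "tree_id", "diameter_cm", "zone", "directly_struck", "died")
  miss <- setdiff(need, names(survey))
  if (length(miss) > 0) {
    stop("survey table is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- survey$directly_struck & survey$zone != "direct"
  if (any(bad)) stop("directly struck trees must carry zone 'direct'")
  unknown <- setdiff(unique(survey$zone), zone_names())
  if (length(unknown) > 0) {
    stop("unknown distance zones: ", paste(unknown, collapse = ", "))
  }
  invisible(survey)
}

#' Partition strikes into the neighbour and direct estimation scopes
#'
#' Neighbour-zone rates can only be computed for strikes inside the
#' censused plot whose location is unambiguous (otherwise the living
#' population per zone is unknown); direct-hit rates use every strike
#' with a directly struck tree, including strikes outside the plot.
#' Both scopes require at least one survey `min_days` or later after the
#' strike.
#'
#' @param survey long-format survey table (one row per tree per survey);
#'   see [read_strike_survey_csv()] for columns.
#' @param cfg an [estimation_config()].
#' @return list with character vectors `neighbour` and `direct` of
#'   qualifying `strike_id`s.
#' @export
filter_strikes <- function(survey, cfg = estimation_config()) {
  validate_survey(survey)
  if (nrow(survey) == 0) return(list(neighbour = character(), direct = character()))
  by_strike <- split(survey, survey$strike_id)
  qualifies <- vapply(by_strike, function(s) any(s$survey_day >= cfg$min_days),
                      logical(1))
  in_scope <- vapply(by_strike, function(s) s$in_plot[1] && s$location_unambiguous[1],
                     logical(1))
  has_direct <- vapply(by_strike, function(s) any(s$directly_struck), logical(1))
  list(neighbour = names(by_strike)[qualifies & in_scope],
       direct = names(by_strike)[qualifies & has_direct])
}

#' Select the earliest qualifying survey of a strike
#'
#' For strikes surveyed several times, mortality is read from the
#' earliest survey at least `min_days` post-strike.
#'
#' @param record survey rows of a single strike.
#' @param cfg an [estimation_config()].
#' @return the selected `survey_day` (scalar).
#' @export
select_survey <- function(record, cfg = estimation_config()) {
  days <- unique(record$survey_day)
  ok <- days[days >= cfg$min_days]
  if (length(ok) == 0) {
    stop("strike has no survey at or after ", cfg$min_days,
         " days; it should have been filtered out")
  }
  min(ok)
}

# outcomes of each strike at its selected survey
selected_outcomes <- function(survey, ids, cfg) {
  if (length(ids) == 0) return(survey[0, , drop = FALSE])
  keep <- survey[survey$strike_id %in% ids, , drop = FALSE]
  do.call(rbind, lapply(split(keep, keep$strike_id), function(s) {
    s[s$survey_day == select_survey(s, cfg), , drop = FALSE]
  }))
}

#' Estimate the size-class x distance-zone mortality-rate table
#'
#' Ring-zone rates pool killed trees over the neighbour-scope strikes and
#' divide by the living population of the same cells from the plot
#' census (`sum(killed) / sum(living)` per cell). Direct rates are the
#' pooled fraction of directly struck trees of each size class that died.
#' Trees of unknown fate are treated as alive (`died = FALSE` in the
#' input), which is conservative.
#'
#' @param survey long-format survey table.
#' @param census census table with columns `strike_id`, `size_class`,
#'   `zone`, `living_count` (living trees per zone around each strike).
#' @param cfg an [estimation_config()].
#' @return A `mortality_rate_table`: data frame with columns
#'   `size_class`, `zone`, `rate`, `killed`, `living`, `fallback`.
#'   Cells with zero living trees get rate 0 and a warning. Direct-hit
#'   cells with no struck trees of that class fall back to the all-size
#'   direct rate (flagged in `fallback`).
#' @export
estimate_rates <- function(survey, census, cfg = estimation_config()) {
  validate_survey(survey)
  sets <- filter_strikes(survey, cfg)
  classes <- size_class_names()
  rings <- zone_names(include_direct = FALSE)

  grid <- expand.grid(size_class = classes, zone = zone_names(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$killed <- 0L
  grid$living <- 0L
  grid$fallback <- FALSE
  key <- function(s, z) match(paste(s, z), paste(grid$size_class, grid$zone))

  # --- ring zones: neighbour scope ---
  outs <- selected_outcomes(survey, sets$neighbour, cfg)
  outs <- outs[!outs$directly_struck, , drop = FALSE]
  if (nrow(outs) > 0) {
    cls <- as.character(classify_size(outs$diameter_cm))
    killed <- table(factor(cls, classes)[outs$died],
                    factor(outs$zone, rings)[outs$died])
    for (s in classes) for (z in rings) {
      grid$killed[key(s, z)] <- killed[s, z]
    }
  }
  cen <- census[census$strike_id %in% sets$neighbour, , drop = FALSE]
  if (nrow(cen) > 0) {
    liv <- tapply(cen$living_count,
                  list(factor(cen$size_class, classes), factor(cen$zone, rings)),
                  sum)
    liv[is.na(liv)] <- 0
    for (s in classes) for (z in rings) {
      grid$living[key(s, z)] <- liv[s, z]
    }
  }

  # --- direct hits: all qualifying strikes with a struck tree ---
  direct <- selected_outcomes(survey, sets$direct, cfg)
  direct <- direct[direct$directly_struck, , drop = FALSE]
  all_rate <- if (nrow(direct) > 0) mean(direct$died) else 0
  for (s in classes) {
    i <- key(s, "direct")
    if (nrow(direct) > 0) {
      sub <- direct[as.character(classify_size(direct$diameter_cm)) == s, ,
                    drop = FALSE]
    } else {
      sub <- direct
    }
    if (nrow(sub) > 0) {
      grid$killed[i] <- sum(sub$died)
      grid$living[i] <- nrow(sub)
    } else {
      grid$fallback[i] <- TRUE
    }
  }

  if (any(grid$killed > grid$living & grid$living > 0)) {
    stop("data integrity: more trees killed than living in a cell")
  }
  grid$rate <- ifelse(grid$living > 0, grid$killed / grid$living, 0)
  # fallback direct cells inherit the pooled all-size direct rate
  grid$rate[grid$fallback & grid$zone == "direct"] <- all_rate
  zero_cells <- grid$living == 0 & grid$zone != "direct"
  if (any(zero_cells & grid$killed == 0) && nrow(cen) > 0) {
    warning(sum(zero_cells), " cell(s) had no living trees; their rate is 0")
  }
  if (any(grid$killed[zero_cells] > 0)) {
    stop("data integrity: killed trees in a cell with no living trees")
  }
  structure(grid[, c("size_class", "zone", "rate", "killed", "living",
                     "fallback")],
            class = c("mortality_rate_table", "data.frame"))
}

#' Look up a mortality rate
#'
#' @param table a `mortality_rate_table` (from [estimate_rates()] or
#'   [rate_table()]).
#' @param size_class,zone cell coordinates (vectorised, recycled).
#' @return numeric rate(s) in `[0, 1]`.
#' @export
rate_lookup <- function(table, size_class, zone) {
  i <- match(paste(size_class, zone), paste(table$size_class, table$zone))
  if (any(is.na(i))) stop("missing rate cell: configuration incomplete")
  table$rate[i]
}

#' Build a mortality-rate table from a matrix of rates
#'
#' @param rates numeric matrix, rows = the four size classes, columns =
#'   the six zones (`direct` first); dimnames optional but checked when
#'   present.
#' @return a `mortality_rate_table` with NA counts.
#' @export
rate_table <- function(rates) {
  classes <- size_class_names()
  zones <- zone_names()
  stopifnot(is.matrix(rates), nrow(rates) == length(classes),
            ncol(rates) == length(zones))
  if (!is.null(rownames(rates))) stopifnot(identical(rownames(rates), classes))
  if (!is.null(colnames(rates))) stopifnot(identical(colnames(rates), zones))
  stopifnot(all(rates >= 0), all(rates <= 1))
  grid <- expand.grid(size_class = classes, zone = zones,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rate <- as.vector(rates)
  grid$killed <- NA_integer_
  grid$living <- NA_integer_
  grid$fallback <- FALSE
  structure(grid, class = c("mortality_rate_table", "data.frame"))
}

#' Mean number of trees killed per lightning strike
#'
#' Direct kills are averaged over the direct scope (all strikes with a
#' struck tree and a qualifying survey) and neighbour kills over the
#' neighbour scope; the two per-strike means are added. Setting
#' `neighbour_scope = "all"` instead averages neighbour kills over every
#' strike with a qualifying survey, which dilutes the mean when
#' out-of-plot strikes have incompletely surveyed neighbourhoods.
#'
#' @param survey long-format survey table.
#' @param cfg an [estimation_config()].
#' @param min_diameter_cm count only trees at least this large (default
#'   10 cm).
#' @param neighbour_scope "filtered" (in-plot, unambiguous strikes) or
#'   "all" (every strike with a qualifying survey).
#' @return list with `total` (mean kills per strike), `per_size` (named
#'   vector), `n_direct`, `n_neighbour`.
#' @export
trees_killed_per_strike <- function(survey, cfg = estimation_config(),
                                    min_diameter_cm = 10,
                                    neighbour_scope = c("filtered", "all")) {
  neighbour_scope <- match.arg(neighbour_scope)
  validate_survey(survey)
  sets <- filter_strikes(survey, cfg)
  neigh_ids <- if (neighbour_scope == "filtered") {
    sets$neighbour
  } else {
    by_strike <- split(survey, survey$strike_id)
    names(by_strike)[vapply(by_strike,
                            function(s) any(s$survey_day >= cfg$min_days),
                            logical(1))]
  }
  if (length(sets$direct) == 0 || length(neigh_ids) == 0) {
    stop("empty direct or neighbour strike set")
  }
  classes <- size_class_names()
  count_kills <- function(outs) {
    outs <- outs[outs$died & outs$diameter_cm >= min_diameter_cm, , drop = FALSE]
    if (nrow(outs) == 0) return(stats::setNames(numeric(4), classes))
    tab <- table(factor(as.character(classify_size(outs$diameter_cm)), classes))
    as.numeric(tab) |> stats::setNames(classes)
  }
  direct <- selected_outcomes(survey, sets$direct, cfg)
  direct_kills <- count_kills(direct[direct$directly_struck, , drop = FALSE])
  neigh <- selected_outcomes(survey, neigh_ids, cfg)
  neigh_kills <- count_kills(neigh[!neigh$directly_struck, , drop = FALSE])
  per_size <- direct_kills / length(sets$direct) + neigh_kills / length(neigh_ids)
  list(total = sum(per_size), per_size = per_size,
       n_direct = length(sets$direct), n_neighbour = length(neigh_ids))
}

#' Bootstrap uncertainty for the rate table
#'
#' Resamples strikes with replacement (independently within the
#' neighbour and direct scopes) and re-estimates the table. Diagnostic
#' only; the point estimate remains [estimate_rates()].
#'
#' @inheritParams estimate_rates
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param probs quantiles to report.
#' @return data frame of per-cell rate quantiles.
#' @export
bootstrap_rates <- function(survey, census, cfg = estimation_config(),
                            n_boot = 1000, seed = 1, probs = c(0.025, 0.975)) {
  validate_survey(survey)
  sets <- filter_strikes(survey, cfg)
  set.seed(seed)
  draws <- replicate(n_boot, {
    # resample strikes within each scope, duplicating under fresh ids
    samp_n <- sample(sets$neighbour, replace = TRUE)
    samp_d <- sample(sets$direct, replace = TRUE)
    relabel <- function(ids, tag) {
      do.call(rbind, lapply(seq_along(ids), function(k) {
        s <- survey[survey$strike_id == ids[k], , drop = FALSE]
        s$strike_id <- paste0(tag, k)
        s
      }))
    }
    sv <- rbind(relabel(samp_n, "n"), relabel(samp_d, "d"))
    cn <- do.call(rbind, lapply(seq_along(samp_n), function(k) {
      cc <- census[census$strike_id == samp_n[k], , drop = FALSE]
      if (nrow(cc) > 0) cc$strike_id <- paste0("n", k)
      cc
    }))
    suppressWarnings(estimate_rates(sv, cn, cfg))$rate
  })
  template <- suppressWarnings(estimate_rates(survey, census, cfg))
  qs <- t(apply(draws, 1, stats::quantile, probs = probs))
  out <- template[, c("size_class", "zone", "rate")]
  for (j in seq_along(probs)) out[[paste0("q", probs[j])]] <- qs[, j]
  out
}

# ---------------------------------------------------------------------------
# File interfaces
# ---------------------------------------------------------------------------

#' Read a strike-survey CSV
#'
#' Expected columns: `strike_id`, `in_plot`, `location_unambiguous`,
#' `survey_day`, `tree_id`, `diameter_cm`, `zone`, `directly_struck`,
#' `died`; one row per tree per survey.
#'
#' @param path CSV path.
#' @return validated survey data frame.
#' @export
read_strike_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$strike_id <- as.character(df$strike_id)
  for (col in c("in_plot", "location_unambiguous", "directly_struck", "died")) {
    if (!is.null(df[[col]])) df[[col]] <- as.logical(df[[col]])
  }
  validate_survey(df)
  df
}

#' Read a census CSV
#'
#' Expected columns: `strike_id`, `size_class`, `zone`, `living_count`.
#'
#' @param path CSV path.
#' @return census data frame.
#' @export
read_census_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strike_id", "size_class", "zone", "living_count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("census CSV is missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(df$living_count < 0)) stop("living_count must be non-negative")
  df$strike_id <- as.character(df$strike_id)
  df
}

#' Write / read a mortality-rate table CSV
#'
#' @param table a `mortality_rate_table`.
#' @param path CSV path.
#' @return `path` (write) or the table (read), invisibly for write.
#' @export
write_rate_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_table_csv
#' @export
read_rate_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("size_class", "zone", "rate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("rate table CSV is missing columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(df$killed)) df$killed <- NA_integer_
  if (is.null(df$living)) df$living <- NA_integer_
  if (is.null(df$fallback)) df$fallback <- FALSE
  structure(df, class = c("mortality_rate_table", "data.frame"))
}
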