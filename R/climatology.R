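# ---------------------------------------------------------------------------
# Cloud-to-ground lightning density climatologies
# ---------------------------------------------------------------------------

EARTH_RADIUS_KM <- 6371

#' Construct a lightning density grid
#'
#' Centre-registered regular lat/lon grid of cloud-to-ground flash
#' densities (flashes km-2 yr-1). The density matrix is laid out
#' `[lat, lon]` with both axes ascending.
#'
#' @param lat,lon ascending vectors of cell-centre coordinates (degrees).
#' @param density matrix `length(lat) x length(lon)`, >= 0.
#' @param resolution_deg cell size (degrees).
#' @param period_years length of the averaging period (years).
#' @return Object of class `density_grid`.
#' @export
density_grid <- function(lat, lon, density, resolution_deg,
                         period_years = 1) {
  stopifnot(is.matrix(density), nrow(density) == length(lat),
            ncol(density) == length(lon), all(density >= 0),
            all(diff(lat) > 0) || length(lat) == 1,
            all(diff(lon) > 0) || length(lon) == 1,
            resolution_deg > 0, period_years > 0)
  structure(list(lat = lat, lon = lon, density = density,
                 resolution_deg = resolution_deg,
                 period_years = period_years),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d cells at %.2f deg, %.2f yr period, mean %.3f flashes/km2/yr\n",
              length(x$lat), length(x$lon), x$resolution_deg,
              x$period_years, mean(x$density)))
  invisible(x)
}

#' Spherical cell areas of a latitude band
#'
#' Exact band formula `R^2 * dlambda * (sin(phi2) - sin(phi1))` with
#' Earth radius 6371 km.
#'
#' @param lat_deg cell-centre latitude(s), degrees.
#' @param resolution_deg cell size, degrees.
#' @return cell area(s) in km2.
#' @export
cell_area_km2 <- function(lat_deg, resolution_deg) {
  half <- resolution_deg / 2
  phi1 <- pmax(lat_deg - half, -90) * pi / 180
  phi2 <- pmin(lat_deg + half, 90) * pi / 180
  EARTH_RADIUS_KM^2 * (resolution_deg * pi / 180) * (sin(phi2) - sin(phi1))
}

normalise_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Grid labelled flash records into a CG density climatology
#'
#' Counts cloud-to-ground flashes per cell over the period and divides by
#' spherical cell area (km2) and period length (years); intra-cloud
#' flashes are excluded. Cells are centre-registered; a flash exactly on
#' a cell boundary goes to the cell to its north-east (the half-open
#' `[edge, edge + res)` convention), except at the domain's north/east
#' rim where it stays in the last cell.
#'
#' @param records data frame with columns `timestamp` (coercible to
#'   Date), `lat`, `lon`, `type` (`"CG"` or `"IC"`).
#' @param resolution_deg cell size, degrees (default 0.5).
#' @param period length-2 vector of Dates (or strings) bounding the
#'   climatology, closed interval.
#' @param lat_range,lon_range grid extent (degrees); default global.
#' @return A [density_grid()]. Records outside the period are excluded
#'   and their count reported via a message.
#' @export
grid_flash_climatology <- function(records, resolution_deg = 0.5,
                                   period = c("2015-06-01", "2021-05-31"),
                                   lat_range = c(-90, 90),
                                   lon_range = c(-180, 180)) {
  need <- c("timestamp", "lat", "lon", "type")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("flash records are missing columns: ", paste(miss, collapse = ", "))
  }
  period <- as.Date(period)
  period_years <- as.numeric(period[2] - period[1] + 1) / 365.25
  if (period_years < 1) stop("climatology period must span at least one year")
  stopifnot(all(records$lat >= -90), all(records$lat <= 90))

  ts <- as.Date(records$timestamp)
  outside <- ts < period[1] | ts > period[2]
  if (any(outside)) {
    message(sum(outside), " flash record(s) outside the period were excluded")
  }
  rec <- records[!outside & records$type == "CG", , drop = FALSE]

  lat <- seq(lat_range[1] + resolution_deg / 2, lat_range[2] - resolution_deg / 2,
             by = resolution_deg)
  lon <- seq(lon_range[1] + resolution_deg / 2, lon_range[2] - resolution_deg / 2,
             by = resolution_deg)
  counts <- matrix(0, length(lat), length(lon))
  if (nrow(rec) > 0) {
    lo <- normalise_lon(rec$lon)
    iy <- pmin(floor((rec$lat - lat_range[1]) / resolution_deg) + 1, length(lat))
    ix <- pmin(floor((lo - lon_range[1]) / resolution_deg) + 1, length(lon))
    keep <- iy >= 1 & ix >= 1
    tab <- table(factor(iy[keep], seq_along(lat)), factor(ix[keep], seq_along(lon)))
    counts <- counts + unclass(tab)
  }
  area <- matrix(cell_area_km2(lat, resolution_deg), length(lat), length(lon))
  density_grid(lat, lon, counts / (area * period_years), resolution_deg,
               period_years)
}

#' Total flashes represented by a climatology
#'
#' Inverts the gridding: `sum(density * cell area * period)`.
#'
#' @param grid a [density_grid()].
#' @return flash count over the grid's period.
#' @export
grid_flash_total <- function(grid) {
  area <- matrix(cell_area_km2(grid$lat, grid$resolution_deg),
                 length(grid$lat), length(grid$lon))
  sum(grid$density * area * grid$period_years)
}

#' Combine a total-lightning grid with a CG-fraction grid
#'
#' The (typically coarser) CG-fraction grid is bilinearly interpolated to
#' the total grid's cell centres and multiplied in. Query points outside
#' the fraction grid's centre lattice are clamped to its edge (nearest
#' edge value); interpolated fractions outside `[0, 1]` are clamped with
#' a warning.
#'
#' @param total_grid a [density_grid()] of total lightning.
#' @param frac_grid a [density_grid()]-shaped object whose `density`
#'   holds CG fractions in `[0, 1]`.
#' @return a [density_grid()] of CG densities on `total_grid`'s lattice.
#' @export
combine_total_with_cg_fraction <- function(total_grid, frac_grid) {
  f <- frac_grid$density
  if (any(f < 0) || any(f > 1)) stop("CG fractions must lie in [0, 1]")
  xp <- pmin(pmax(rep(total_grid$lon, each = length(total_grid$lat)),
                  min(frac_grid$lon)), max(frac_grid$lon))
  yp <- pmin(pmax(rep(total_grid$lat, times = length(total_grid$lon)),
                  min(frac_grid$lat)), max(frac_grid$lat))
  # interp2 wants Z as length(y) x length(x): our [lat, lon] layout already is
  fi <- pracma::interp2(x = frac_grid$lon, y = frac_grid$lat, Z = f,
                        xp = xp, yp = yp, method = "linear")
  if (any(fi < -1e-12) || any(fi > 1 + 1e-12)) {
    warning("interpolated CG fractions outside [0, 1] were clamped")
  }
  fi <- pmin(pmax(fi, 0), 1)
  frac_on_total <- matrix(fi, length(total_grid$lat), length(total_grid$lon))
  density_grid(total_grid$lat, total_grid$lon,
               total_grid$density * frac_on_total,
               total_grid$resolution_deg, total_grid$period_years)
}

#' Effective lightning density over partially forested cells
#'
#' Lightning is assumed to fall with equal density on natural
#' (tree-covered) and agricultural land, but only strikes over natural
#' land kill trees. Simulated patches therefore receive the full cell
#' density, while regional kill totals scale with the natural-land
#' fraction.
#'
#' @param cell_density_km2_yr CG flash density of the cell.
#' @param natural_land_fraction fraction of the cell that is natural
#'   land, in `[0, 1]`.
#' @return list with `patch_density_km2_yr` (unchanged density driving
#'   each simulated patch) and `area_scale` (multiplier for regional
#'   totals).
#' @export
effective_density <- function(cell_density_km2_yr, natural_land_fraction) {
  stopifnot(all(cell_density_km2_yr >= 0),
            all(natural_land_fraction >= 0), all(natural_land_fraction <= 1))
  list(patch_density_km2_yr = cell_density_km2_yr,
       area_scale = natural_land_fraction)
}

# ---------------------------------------------------------------------------
# File interfaces (plain-text grids)
# ---------------------------------------------------------------------------

#' Write / read a density grid as CSV
#'
#' Long format with columns `lat`, `lon`, `density`; grid metadata
#' (`resolution_deg`, `period_years`) travels in a `#`-prefixed header
#' line so a grid round-trips through one plain-text file.
#'
#' @param grid a [density_grid()].
#' @param path CSV path.
#' @return `path` (write) or a [density_grid()] (read).
#' @export
write_grid_csv <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# density_grid resolution_deg=%.10g period_years=%.10g",
                     grid$resolution_deg, grid$period_years), con)
  df <- data.frame(lat = rep(grid$lat, times = length(grid$lon)),
                   lon = rep(grid$lon, each = length(grid$lat)),
                   density = as.vector(grid$density))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# density_grid")) {
    stop("not a density grid CSV (missing header line)")
  }
  get_num <- function(key) {
    m <- regmatches(header, regexpr(paste0(key, "=[0-9.eE+-]+"), header))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  df <- utils::read.csv(path, comment.char = "#")
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  dens <- matrix(NA_real_, length(lat), length(lon))
  dens[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$density
  density_grid(lat, lon, dens, get_num("resolution_deg"),
               get_num("period_years"))
}
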