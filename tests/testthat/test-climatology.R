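test_that("spherical cell areas tile the globe", {
  res <- 2.5
  lat <- seq(-90 + res / 2, 90 - res / 2, by = res)
  band <- cell_area_km2(lat, res)
  n_lon <- 360 / res
  expect_equal(sum(band) * n_lon, 4 * pi * 6371^2, tolerance = 1e-9)
  # areas shrink towards the poles
  expect_true(all(diff(band[lat > 0]) < 0))
})

test_that("flash gridding counts CG flashes per cell-area-year", {
  one <- data.frame(timestamp = "2016-06-01", lat = 9.1, lon = -79.8,
                    type = "CG")
  g <- grid_flash_climatology(one, resolution_deg = 1,
                              period = c("2016-01-01", "2016-12-31"),
                              lat_range = c(9, 10), lon_range = c(-80, -79))
  a <- cell_area_km2(9.5, 1)
  expect_equal(as.numeric(g$density), (1 / a) / g$period_years)
  expect_equal(grid_flash_total(g), 1, tolerance = 1e-9)

  # intra-cloud flashes never reach the grid
  ic <- data.frame(timestamp = rep("2016-06-01", 5), lat = runif(5, 9, 10),
                   lon = runif(5, -80, -79), type = "IC")
  g_ic <- grid_flash_climatology(ic, 1, c("2016-01-01", "2016-12-31"),
                                 c(9, 10), c(-80, -79))
  expect_true(all(g_ic$density == 0))

  # records outside the period are excluded (and reported)
  late <- rbind(one, data.frame(timestamp = "2020-01-01", lat = 9.1,
                                lon = -79.8, type = "CG"))
  expect_message(
    g2 <- grid_flash_climatology(late, 1, c("2016-01-01", "2016-12-31"),
                                 c(9, 10), c(-80, -79)),
    "excluded")
  expect_equal(grid_flash_total(g2), 1, tolerance = 1e-9)

  expect_error(grid_flash_climatology(one, 1, c("2016-01-01", "2016-03-01")),
               "at least one year")
})

test_that("boundary flashes go to the north-east cell", {
  # flash exactly on the shared corner of four 1-degree cells
  corner <- data.frame(timestamp = "2016-06-01", lat = 10, lon = -79,
                       type = "CG")
  g <- grid_flash_climatology(corner, 1, c("2016-01-01", "2016-12-31"),
                              lat_range = c(9, 11), lon_range = c(-80, -78))
  hit <- which(g$density > 0, arr.ind = TRUE)
  expect_equal(g$lat[hit[1]], 10.5)  # north
  expect_equal(g$lon[hit[2]], -78.5) # east
})

test_that("a known Poisson intensity field is recovered", {
  lat <- seq(-0.25, 0.25, by = 0.5)
  lon <- seq(-0.25, 0.25, by = 0.5)
  intensity <- matrix(c(0.5, 2, 0, 1), 2, 2)
  igrid <- density_grid(lat, lon, intensity, 0.5)
  rec <- gen_flash_records(igrid, years = 4, seed = 31, cg_fraction = 1)
  g <- grid_flash_climatology(rec, 0.5, c("2016-01-01", "2019-12-31"),
                              lat_range = c(-0.5, 0.5),
                              lon_range = c(-0.5, 0.5))
  for (i in 1:2) for (j in 1:2) {
    n_exp <- intensity[i, j] * cell_area_km2(lat[i], 0.5) * 4
    if (n_exp == 0) {
      expect_equal(g$density[i, j], 0)
    } else {
      se <- sqrt(n_exp) / (cell_area_km2(lat[i], 0.5) * g$period_years)
      expect_lt(abs(g$density[i, j] - intensity[i, j] * 4 / g$period_years),
                3 * se)
    }
  }
  # total flashes reconstructed from the grid equal the record count
  expect_equal(grid_flash_total(g), sum(rec$type == "CG"), tolerance = 1e-6)
})

test_that("total x CG-fraction combination interpolates bilinearly", {
  lat_f <- c(-1, 1)
  lon_f <- c(-1, 1)
  total <- density_grid(seq(-0.75, 0.75, 0.5), seq(-0.75, 0.75, 0.5),
                        matrix(10, 4, 4), 0.5)

  uni <- density_grid(lat_f, lon_f, matrix(0.3, 2, 2), 2)
  expect_equal(combine_total_with_cg_fraction(total, uni)$density,
               matrix(3, 4, 4))
  all1 <- density_grid(lat_f, lon_f, matrix(1, 2, 2), 2)
  expect_equal(combine_total_with_cg_fraction(total, all1)$density,
               total$density)

  # checkerboard coarse fractions against a hand-written bilinear oracle
  chk <- density_grid(lat_f, lon_f, matrix(c(0, 1, 1, 0), 2, 2), 2)
  out <- combine_total_with_cg_fraction(total, chk)
  bilin <- function(x, y) {
    # corners: f(-1,-1)=0, f(1,-1)=1, f(-1,1)=1, f(1,1)=0 (lat, lon)
    tx <- (x + 1) / 2
    ty <- (y + 1) / 2
    (1 - ty) * ((1 - tx) * 0 + tx * 1) + ty * ((1 - tx) * 1 + tx * 0)
  }
  for (i in seq_along(total$lat)) for (j in seq_along(total$lon)) {
    expect_equal(out$density[i, j],
                 10 * bilin(total$lat[i], total$lon[j]), tolerance = 1e-9)
  }
  # interpolation preserves the fraction range
  expect_true(all(out$density >= 10 * min(chk$density) - 1e-9))
  expect_true(all(out$density <= 10 * max(chk$density) + 1e-9))

  bad <- density_grid(lat_f, lon_f, matrix(0.5, 2, 2), 2)
  bad$density[1, 1] <- 1.4
  expect_error(combine_total_with_cg_fraction(total, bad), "\\[0, 1\\]")
})

test_that("natural-land fraction scales totals but not patch densities", {
  e1 <- effective_density(12.7, 1)
  expect_equal(e1$patch_density_km2_yr, 12.7)
  expect_equal(e1$area_scale, 1)
  e0 <- effective_density(12.7, 0)
  expect_equal(e0$area_scale, 0)
  eh <- effective_density(12.7, 0.5)
  expect_equal(eh$patch_density_km2_yr, 12.7)
  expect_equal(eh$area_scale, 0.5)
})

test_that("density grids round-trip through CSV", {
  lat <- seq(-4.75, 4.75, 2.5)
  lon <- seq(0.25, 5.25, 2.5)
  set.seed(2)
  g <- density_grid(lat, lon, matrix(runif(length(lat) * length(lon), 0, 20),
                                     length(lat), length(lon)),
                    2.5, period_years = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, f)
  g2 <- read_grid_csv(f)
  expect_equal(g2$lat, g$lat)
  expect_equal(g2$lon, g$lon)
  expect_equal(g2$density, g$density)
  expect_equal(g2$resolution_deg, 2.5)
  expect_equal(g2$period_years, 6)
  expect_error(read_grid_csv(withr::local_tempfile(fileext = ".csv",
                                                   lines = "lat,lon")),
               "header")
})
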