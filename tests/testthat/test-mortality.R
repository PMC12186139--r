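test_that("vulnerability scales rates multiplicatively with a cap at 1", {
  trop <- default_pfts()$TrBE
  conifer <- default_pfts()$NE
  expect_equal(effective_rate(0.2, trop), 0.2)
  expect_equal(effective_rate(0.2, conifer), 0.36)
  expect_equal(effective_rate(0.9, conifer), 1)
  expect_error(effective_rate(1.2, trop))
})

test_that("a centred strike kills rate x density x ring-area per zone", {
  g <- schematic_stand()
  cfg <- lightning_config(uniform_rate_table(0.1))
  geom <- geometry_config()
  strike <- data.frame(distance_m = 0, angle_rad = 0, in_patch = TRUE)
  res <- apply_strike(g, strike, cfg, geom)

  # independent hand computation: full annuli inside the patch disc
  a1 <- pi * 100                      # 0-10 m ring
  a2 <- geom$patch_area_m2 - pi * 100 # 10-20 m ring truncated at the edge
  for (dd in list(c(20, 0.006), c(45, 0.012), c(80, 0.004))) {
    cls <- as.character(classify_size(dd[1]))
    ring_kills <- res$kills[res$kills$size_class == cls &
                              res$kills$zone != "direct", ]
    expect_equal(sum(ring_kills$individuals), 0.1 * dd[2] * (a1 + a2),
                 tolerance = 1e-9)
  }
  # direct hit: tallest cohort is the 80 cm one, expected-value kill 0.1
  direct <- res$kills[res$kills$zone == "direct", ]
  expect_equal(direct$size_class, "large")
  expect_equal(direct$individuals, 0.1)
  # total ring kills: rate x total density x patch area
  expect_equal(sum(res$kills$individuals[res$kills$zone != "direct"]),
               0.1 * 0.022 * 1000, tolerance = 1e-9)
})

test_that("kills scale linearly with vulnerability below the cap", {
  g_trop <- schematic_stand()
  g_conif <- toy_group(c(20, 45, 80), c(0.006, 0.012, 0.004),
                       pft_name = "NE")
  cfg <- lightning_config(uniform_rate_table(0.1))
  strike <- data.frame(distance_m = 10, angle_rad = 0, in_patch = TRUE)
  k_trop <- apply_strike(g_trop, strike, cfg)$kills
  k_conif <- apply_strike(g_conif, strike, cfg)$kills
  expect_equal(sum(k_conif$individuals), 1.8 * sum(k_trop$individuals),
               tolerance = 1e-9)
})

test_that("an empty group yields no kills and missing rate cells error", {
  empty <- patch_group(list(patch()))
  cfg <- lightning_config(uniform_rate_table(0.1))
  strike <- data.frame(distance_m = 0, angle_rad = 0, in_patch = TRUE)
  expect_equal(nrow(apply_strike(empty, strike, cfg)$kills), 0)

  partial <- suppressWarnings(
    estimate_rates(survey_row("A", "a", 70, "direct", TRUE),
                   data.frame(strike_id = character(), size_class = character(),
                              zone = character(), living_count = integer())))
  partial <- partial[partial$zone != "z40_45", ]
  expect_error(lightning_config(partial), "missing rate cell")
})

test_that("stems are conserved and densities never go negative", {
  for (stochastic in c(FALSE, TRUE)) {
    set.seed(31)
    g <- gen_stand("bci_like", seed = 17)
    cfg <- lightning_config(synthetic_rate_table(),
                            stochastic_kills = stochastic)
    geom <- geometry_config()
    for (i in 1:40) {
      before <- group_totals(g)$stems
      res <- simulate_year(g, 500, cfg, geom) # inflated density: many strikes
      g <- res$group
      after <- group_totals(g)$stems
      expect_equal(before - after, sum(res$kills$individuals),
                   tolerance = 1e-9)
      for (p in g$patches) expect_true(all(p$cohorts$density_m2 >= 0))
    }
  }
})

test_that("kills are monotone in density, rates, and vulnerability", {
  cfg_lo <- lightning_config(uniform_rate_table(0.05))
  cfg_hi <- lightning_config(uniform_rate_table(0.10))
  g <- schematic_stand()
  g2 <- toy_group(c(20, 45, 80), 2 * c(0.006, 0.012, 0.004))
  e_base <- kills_per_strike_expectation(g, cfg_lo)
  e_rate <- kills_per_strike_expectation(g, cfg_hi)
  e_dens <- kills_per_strike_expectation(g2, cfg_lo)
  e_vuln <- kills_per_strike_expectation(
    toy_group(c(20, 45, 80), c(0.006, 0.012, 0.004), pft_name = "NE"), cfg_lo)
  expect_true(all(e_rate$per_size >= e_base$per_size))
  expect_gt(e_rate$total, e_base$total)
  expect_gt(e_dens$total, e_base$total)
  expect_gt(e_vuln$total, e_base$total)
  # ring kills are exactly linear in density (direct term unchanged)
  expect_equal(e_dens$ring_per_size, 2 * e_base$ring_per_size,
               tolerance = 1e-12)
  expect_equal(e_dens$direct_per_size, e_base$direct_per_size)
  # and exactly linear in the rate table below the cap
  expect_equal(e_rate$ring_per_size, 2 * e_base$ring_per_size,
               tolerance = 1e-12)
})

test_that("Monte-Carlo kills per strike agree with the quadrature", {
  g <- schematic_stand()
  cfg <- lightning_config(synthetic_rate_table())
  geom <- geometry_config()
  expected <- kills_per_strike_expectation(g, cfg, geom)

  set.seed(5)
  n_mc <- 4000
  strikes <- sample_strike(geom, n_mc)
  per_strike <- vapply(seq_len(n_mc), function(i) {
    sum(apply_strike(g, strikes[i, ], cfg, geom)$kills$individuals)
  }, numeric(1))
  se <- sd(per_strike) / sqrt(n_mc)
  expect_lt(abs(mean(per_strike) - expected$total), 3 * se)

  # zero densities give a zero expectation
  e0 <- kills_per_strike_expectation(patch_group(list(patch())), cfg, geom)
  expect_equal(e0$total, 0)
})

test_that("simulated strike frequency matches the analytic probability", {
  g <- geometry_config()
  set.seed(2)
  counts <- annual_strike_count(12.7, g, n = 2e5)
  p_hat <- mean(counts >= 1)
  p_true <- prob_strike_ge1(12.7, g)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 2e5))
  expect_lt(p_true, 0.15)
})

test_that("a zero flash density leaves the group untouched", {
  g <- gen_stand("bci_like", seed = 2)
  cfg <- lightning_config(synthetic_rate_table())
  res <- simulate_year(g, 0, cfg)
  expect_equal(res$n_strikes, rep(0L, 5))
  expect_identical(res$group, g)
  expect_equal(nrow(res$kills), 0)
})

test_that("merge-factor sweep shifts strikes towards large trees", {
  frac_large <- vapply(c(1, 5, 10), function(m) {
    strike_size_distribution(m, n_landscapes = 40, seed = 19)[["large"]]
  }, numeric(1))
  expect_true(all(diff(frac_large) > 0))
  expect_lt(frac_large[1], 0.5)
  expect_gt(frac_large[3], 0.9)
})
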