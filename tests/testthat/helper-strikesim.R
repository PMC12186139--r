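# Shared helpers for the test suite. Oracles here are deliberately
# independent of the implementation paths they check.

# Monte-Carlo oracle for the intersection area of two discs: uniform
# points in the disc of radius R about the origin, classified against a
# disc of radius r centred at (d, 0).
mc_lens_area <- function(R, r, d, n = 2e5) {
  rho <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  x <- rho * cos(th)
  y <- rho * sin(th)
  mean((x - d)^2 + y^2 <= r^2) * pi * R^2
}

# A rate table with one uniform rate everywhere.
uniform_rate_table <- function(p) rate_table(matrix(p, 4, 6))

# Single-patch group holding one cohort per supplied diameter.
toy_group <- function(diameters, densities, pft_name = "TrBE",
                      ages = NULL, n_patches = 1) {
  if (is.null(ages)) ages <- rep(50, length(diameters))
  ch <- cohorts(rep(pft_name, length(diameters)), ages, diameters, densities)
  patches <- c(list(patch(ch)),
               replicate(n_patches - 1, patch(cohorts()), simplify = FALSE))
  patch_group(patches)
}

# The schematic tropical stand: no tiny trees, 0.006 small, 0.012
# medium, 0.004 large stems per m2, as one cohort per class.
schematic_stand <- function(n_patches = 1) {
  toy_group(diameters = c(20, 45, 80), densities = c(0.006, 0.012, 0.004),
            n_patches = n_patches)
}

# Hand-built survey row(s).
survey_row <- function(strike_id, tree_id, diameter_cm, zone, died,
                       survey_day = 400, in_plot = TRUE,
                       location_unambiguous = TRUE,
                       directly_struck = identical(zone, "direct")) {
  data.frame(strike_id = strike_id, in_plot = in_plot,
             location_unambiguous = location_unambiguous,
             survey_day = survey_day, tree_id = tree_id,
             diameter_cm = diameter_cm, zone = zone,
             directly_struck = directly_struck, died = died,
             stringsAsFactors = FALSE)
}
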