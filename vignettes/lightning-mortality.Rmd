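---
title: "Modelling lightning-induced tree mortality on cohort-structured stands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lightning-induced tree mortality on cohort-structured stands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strikesim)
```

## The problem

Cloud-to-ground (CG) lightning is a chronic, small-scale disturbance in
closed forests. A strike usually hits the tallest tree in its immediate
surroundings, but the discharge can jump between touching or nearby
crowns ("flashover"), so a single strike often kills several trees
within a radius of roughly 45 m, with mortality probabilities that
increase with stem diameter and decrease with distance from the struck
tree. Because the damage is spread over months and rarely leaves
conspicuous scars, lightning mortality is chronically under-attributed
in field data, and it is absent from most vegetation models.

`strikesim` packages the ingredients needed to represent this process
on cohort-structured stands of the kind dynamic vegetation models use:

1. **Rate estimation** (`estimate_rates()`): turn per-strike,
   per-tree survey records plus a plot census into an empirical
   mortality-rate table indexed by size class x distance zone.
2. **Strike geometry** (`geometry_config()`, `sample_strike()`,
   `zone_area_in_patch()`): place strikes around a model patch and
   compute how much of each distance ring falls inside it.
3. **Lightning kills** (`apply_strike()`, `simulate_year()`): apply the
   rate table to the cohorts of a patch group, killing the directly
   struck individual and neighbours by zone.
4. **Demography** (`step_year()`, `run_stand_simulation()`): a minimal
   cohort engine so multi-century runs produce cause-attributed
   mortality ledgers.
5. **Climatology** (`grid_flash_climatology()`,
   `combine_total_with_cg_fraction()`): build gridded CG flash
   densities that drive the strike-count model.

## Size classes, zones, and the empirical rate table

Stems are classified by diameter into tiny (1–10 cm), small (10–30 cm),
medium (30–60 cm) and large (> 60 cm); intervals are half-open with the
boundaries 10/30/60 assigned upward, so the classes partition all
diameters at or above the 1 cm census threshold. Distances from the
strike are either `direct` (the struck tree itself) or one of five
rings out to the 45 m flashover reach: 0–10, 10–20, 20–30, 30–40 and
40–45 m.

The estimator reproduces a survey protocol in which strikes are located
in near-real time and their neighbourhood is revisited after roughly a
year. Three scoping rules matter and are implemented exactly:

* **Neighbour-zone rates** need the living population per zone, which
  only a plot census provides. They therefore use only strikes inside
  the censused plot whose location is unambiguous and which have a
  survey at least `min_days` (default 346) after the strike.
* **Direct-hit rates** only need the struck trees themselves, so every
  strike with a directly struck tree and a qualifying survey counts,
  including strikes outside the plot.
* For strikes surveyed repeatedly, the **earliest qualifying survey**
  is used, so every strike contributes mortality over a comparable
  exposure window.

Rates are pooled — total killed divided by total living per cell —
rather than averaged per strike; a killed count exceeding the living
population is rejected as a data-integrity error. Cells with no living
trees get rate 0 with a warning (never `NaN`, so the simulator cannot
consume undefined rates). Direct cells with no struck trees of that
size fall back to the all-size direct rate and are flagged. Trees of
unknown fate should be coded as alive; the estimate is then
conservative. `bootstrap_rates()` (strike-level resampling) provides
diagnostic uncertainty; it is not part of the point estimate.

## Strike geometry

Model patches are aspatial, but the flashover reach gives them an
implicit footprint: modelling the 1000 m² patch as a disc (radius
17.8 m) and extending it by the 45 m reach yields a strike-target disc
of radius

```{r}
extended_radius(1000, 45)
```

metres and area

```{r}
extended_area(1000, 45)
```

m², about 12.4 times the patch itself. Strikes are sampled uniformly
over this extended disc, so most land outside the patch and the
high-mortality inner rings often miss it entirely — the geometry, not a
tuning constant, is what keeps simulated lightning mortality modest.

The annual number of strikes on the disc is binomial with one Bernoulli
trial per day: `N ~ Binomial(365, lambda/365)` with
`lambda = density x extended area`. At a tropical density of
12.7 flashes km⁻² yr⁻¹:

```{r}
prob_strike_ge1(12.7, geometry_config()) * 100
```

percent of patch-years see at least one strike. A Poisson option is
provided (`method = "poisson"`); at realistic densities the two agree
to better than 0.1%, and the binomial converges to the Poisson as
`n_trials` grows.

The part of each ring inside the patch is an intersection of two discs
(`lens_area()`, the standard two-segment closed form, clamped against
floating-point drift at tangency). The six ring areas of any strike sum
exactly to the overlap of the 45 m reach disc with the patch — an
identity the test suite checks against an independent Monte-Carlo
point-classification oracle.

## Kills on a patch group

Cohort models often develop limited within-patch structure, so `M`
patches (default 5) are merged for the lightning calculation: a strike
anywhere in the group hits one individual of the **tallest cohort
across all member patches** (which can be a small or even tiny tree if
nothing taller exists), and every cohort is treated as present on the
struck patch at `density / M`. Expected kills per cohort and ring are

```
kills = (density / M) x ring_area_inside_patch x effective_rate
```

with `effective_rate = min(rate x vulnerability, 1)`. The vulnerability
multiplier is 1.0 for tropical PFTs (the rates were measured in a
tropical forest), 1.5 for extratropical broadleaves and 1.8 for
needleleaves, reflecting higher electrical resistance of
non-tropical/coniferous species; it applies to direct and ring rates
alike. All kills of one strike are evaluated against the pre-strike
densities, then subtracted jointly, capped so no cohort goes negative.

Two kill modes exist. The default is expected-value (fractional) kills,
matching the continuous densities of cohort-based models and making
per-strike results deterministic given the strike location. A
stochastic mode draws integer kills per (cohort, zone) for
individual-based bookkeeping; stem conservation holds exactly in both.

`kills_per_strike_expectation()` integrates the ring-kill expression
over the uniform strike-location distribution (radial quadrature,
2001 nodes by default) and adds the direct term weighted by the
probability `patch_area / extended_area` that a strike lands inside the
patch. This gives a noise-free per-strike expectation used by the
gridded upscaling and by tests that compare Monte-Carlo simulation
against quadrature.

The merge factor is configurable (1, 5, 10) because it controls the
size distribution of struck trees: with more patches merged, the
tallest-cohort search spans more of the landscape and strikes shift
towards large trees. `strike_size_distribution()` measures this on
synthetic landscapes; the ordering (fraction of strikes hitting large
trees increasing with `M`) is asserted in the tests.

## The demography stand-in

To attribute lightning mortality against other causes over centuries,
the package includes a deliberately minimal cohort demography — it is a
stand-in for a full vegetation model, not a port of one. Per patch and
year, in order: diameter growth, background mortality, self-thinning,
generic stand-destroying disturbance, then lightning at group level,
then establishment.

* **Growth**: `dD = g (1 - D/D_max)` cm yr⁻¹ per PFT (defaults: 0.6 and
  120 for the tropical broadleaf PFT), giving large trees at realistic
  ages of one to a few centuries.
* **Background mortality**: annual hazard
  `h(age) = (0.2 + 1.832 (age/L)^4) / L`, with `L` the PFT longevity.
  The slope 1.832 is the numerical solution making the mean age at
  death equal `L`; the test suite verifies this to 10% with simulated
  lifetimes. The hazard form is an interpretation (the source model's
  exact curve is internal) and is isolated in
  `background_mortality_rate()` for easy replacement.
* **Self-thinning**: when the crown-area index (crown radius
  `0.5 + 0.09 D` m) exceeds 3, all cohorts are thinned proportionally
  back to the ceiling. This replaces growth-efficiency mortality, which
  needs a full production model — the largest simplification in the
  package, and the reason small-tree mortality here should not be
  compared quantitatively to field data.
* **Disturbance**: each patch is destroyed with probability
  `1/interval` per year (default interval 150 years).
* **Establishment**: new 1 cm cohorts (0.005 stems m⁻²) appear when a
  patch's crown-area index falls below 1.2, no more than once per
  decade per PFT — a light proxy consistent with recruitment pulses
  after severe disturbance.

Every killed stem is booked exactly once in a `MortalityLedger` under
one cause (lightning, background, disturbance, self_thinning; a fire
slot is kept for comparability but never filled). `attribute()` turns
the ledger into percentage shares per size class and for killed
biomass, which sum to 100 by construction.

**RNG policy.** Each simulated year draws one integer from the main
stream as the seed of a lightning substream and restores the main
stream afterwards. Consequences: (i) a run with all lightning rates set
to 0 is bit-for-bit identical to a run with lightning disabled; (ii)
paired on/off runs share identical demography noise, so lightning's
effect on biomass is isolated by construction and must be non-positive
every year — both are asserted in the tests.

## CG lightning climatologies

Two routes produce the flash-density grids that drive the strike-count
model, mirroring the two kinds of observational product available:

* `grid_flash_climatology()` bins labelled flash records (CG vs
  intra-cloud) into a centre-registered lat/lon grid, dividing counts
  by spherical cell area (band formula, Earth radius 6371 km) and
  period length. Records on a cell boundary go to the north-east cell
  (half-open `[edge, edge + res)` intervals); intra-cloud flashes and
  records outside the closed period are excluded (the latter with a
  reported count). The default period (June 2015 – May 2021) reflects a
  window of stable detection efficiency in ground-network data.
* `combine_total_with_cg_fraction()` converts a total-lightning grid to
  CG by multiplying with a CG-fraction field, bilinearly interpolated
  from its (typically coarser) native grid to the total grid's cell
  centres; queries beyond the fraction grid's centre lattice clamp to
  the edge value, and interpolated fractions are clamped to `[0, 1]`
  with a warning.

Over partially cultivated cells, lightning is assumed to fall equally
on natural and agricultural land while only strikes over natural land
kill trees: patches receive the full cell density and regional totals
scale with the natural-land fraction (`effective_density()`), making
kill totals exactly linear in that fraction.

No NetCDF library is used: grids are exchanged as long-format CSV with
a one-line metadata header (`write_grid_csv()` / `read_grid_csv()`),
which keeps every artefact plain text and diffable.

## What the synthetic generators emulate — and what they do not

`gen_strike_survey()` inverts the estimator: living counts per cell are
Poisson around a stand profile times the annulus area, deaths are
Bernoulli with the true rate, and a configurable fraction of records
deliberately fails each filter. Because the generator and estimator
share only the file formats, recovering the truth table within exact
binomial acceptance regions is a genuine round-trip test of the
estimator, not a tautology.

`gen_stand()` draws cohorts whose class densities match the requested
profile exactly; the `bci_like` profile uses the schematic tropical
densities 0 / 0.006 / 0.012 / 0.004 stems m⁻² (tiny/small/medium/
large). Classes occupy only a subset of patches (large trees ~20% of
them, chosen once so that single patches usually lack a large cohort),
which is what makes the merge-factor sensitivity reproducible. The
built-in rate table (`synthetic_rate_table()`) is shaped like field
observations — increasing with size, decaying with distance — but its
values are arbitrary and labelled synthetic throughout.

What passing tests therefore show: the estimator, geometry, kill
arithmetic, bookkeeping and upscaling are internally correct and
mutually consistent. What they do not show: that the demography
reproduces any particular forest's size structure or mortality budget —
that calibration lives with the full vegetation model and field data,
both out of scope here.

## Numerical choices and degenerate inputs

* Disc intersections use the closed-form segment decomposition with
  `acos` arguments clamped to `[-1, 1]`; containment and disjoint cases
  short-circuit, so tangency is exact rather than `NaN`.
* The per-strike expectation uses trapezoidal quadrature on 2001 radial
  nodes; against Monte-Carlo with 10⁶ classification points it agrees
  within three standard errors.
* Tallest-cohort ties break by larger diameter, then earlier
  (patch, cohort) index — deterministic and permutation-stable.
* Empty groups, empty cohort tables, zero densities, zero rates and
  zero flash densities are all valid inputs and produce empty kill
  tables rather than errors; a flash density implying more than one
  strike per Bernoulli trial errors with advice to raise `n_trials`.
* Cohorts thinner than 10⁻¹⁰ stems m⁻² are pruned to keep century runs
  bounded.
* Problem sizes in the test suite (10⁶ Monte-Carlo patch-years for the
  strike probability, 2 x 10⁶ points per geometry oracle, 100 recovery
  replicates of 40 strikes, stand runs of 80–1000 years with 5
  patches) were chosen once as the smallest sizes at which the
  stochastic assertions have comfortable margins; they are the
  package's own reproducibility choices.

## Known limitations

* Delayed (multi-year) mortality of damaged survivors, secondary biotic
  mortality and lightning-ignited fire are not modelled; the ledger's
  fire slot exists only to keep attributions comparable.
* Terrain effects on strike placement are ignored; placement is uniform
  over the extended disc.
* The demography's self-thinning term and establishment proxy are
  simplifications; absolute mortality attributions from long runs
  should be read qualitatively.
* Detection-efficiency correction of flash networks is out of scope;
  the climatology divides by the whole period rather than averaging
  per-year grids, which is identical for complete years.
* Whether merged patches should share a single sampled strike location
  is ambiguous in the source description; locations are sampled
  independently per patch here.
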