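test_that("strike filtering applies the scope and survey-day rules", {
  empty <- survey_row("x", "t", 20, "z0_10", FALSE)[0, ]
  sets <- filter_strikes(empty)
  expect_equal(sets$neighbour, character())
  expect_equal(sets$direct, character())

  sv <- rbind(
    survey_row("A", "a1", 70, "direct", TRUE, survey_day = 400),
    survey_row("A", "a2", 20, "z0_10", TRUE, survey_day = 400),
    survey_row("B", "b1", 70, "direct", TRUE, survey_day = 200),  # too early
    survey_row("C", "c1", 15, "z10_20", TRUE, survey_day = 346,
               in_plot = FALSE),                                  # out of plot
    survey_row("D", "d1", 40, "direct", FALSE, survey_day = 500,
               location_unambiguous = FALSE)                      # ambiguous
  )
  sets <- filter_strikes(sv)
  expect_equal(sets$neighbour, "A")
  # direct scope keeps ambiguous/out-of-plot strikes with a struck tree
  expect_setequal(sets$direct, c("A", "D"))

  all_ok <- rbind(survey_row("A", "a", 20, "z0_10", TRUE),
                  survey_row("B", "b", 20, "z0_10", FALSE))
  expect_setequal(filter_strikes(all_ok)$neighbour, c("A", "B"))

  # integrity: a directly struck tree must be in the direct zone
  bad <- survey_row("E", "e", 20, "z0_10", TRUE)
  bad$directly_struck <- TRUE
  expect_error(filter_strikes(bad), "zone 'direct'")
})

test_that("the earliest qualifying survey is selected, boundary inclusive", {
  rec <- rbind(survey_row("A", "t", 20, "z0_10", FALSE, survey_day = 200),
               survey_row("A", "t", 20, "z0_10", TRUE, survey_day = 400),
               survey_row("A", "t", 20, "z0_10", TRUE, survey_day = 500))
  expect_equal(select_survey(rec), 400)
  expect_equal(select_survey(survey_row("B", "t", 20, "z0_10", TRUE,
                                        survey_day = 346)), 346)
  expect_error(select_survey(survey_row("C", "t", 20, "z0_10", TRUE,
                                        survey_day = 100)), "filtered")
})

test_that("rate estimation divides pooled kills by pooled living counts", {
  sv <- rbind(
    survey_row("A", "d1", 70, "direct", TRUE),
    survey_row("A", paste0("k", 1:2), c(15, 20), "z0_10", TRUE)
  )
  census <- data.frame(strike_id = "A", size_class = "small", zone = "z0_10",
                       living_count = 10)
  tab <- suppressWarnings(estimate_rates(sv, census))
  expect_s3_class(tab, "mortality_rate_table")
  expect_equal(rate_lookup(tab, "small", "z0_10"), 0.2)
  expect_equal(rate_lookup(tab, "large", "direct"), 1)
  # untouched ring cells are zero
  expect_equal(rate_lookup(tab, "large", "z40_45"), 0)
  # direct cells without struck trees fall back to the pooled direct rate
  expect_true(tab$fallback[tab$size_class == "tiny" & tab$zone == "direct"])
  expect_equal(rate_lookup(tab, "tiny", "direct"), 1)

  # no deaths anywhere -> all-zero table
  sv0 <- rbind(survey_row("A", "d1", 70, "direct", FALSE),
               survey_row("A", "s1", 15, "z0_10", FALSE))
  tab0 <- suppressWarnings(estimate_rates(sv0, census))
  expect_true(all(tab0$rate == 0))

  # killed > living is a data-integrity error
  census_bad <- data.frame(strike_id = "A", size_class = "small",
                           zone = "z0_10", living_count = 1)
  expect_error(estimate_rates(sv, census_bad), "integrity")
})

test_that("rates are invariant to row order and census row splitting", {
  gen <- gen_strike_survey(n_strikes = 40, seed = 5)
  tab <- suppressWarnings(estimate_rates(gen$survey, gen$census))

  set.seed(1)
  shuf <- gen$survey[sample(nrow(gen$survey)), ]
  cen_shuf <- gen$census[sample(nrow(gen$census)), ]
  tab2 <- suppressWarnings(estimate_rates(shuf, cen_shuf))
  expect_equal(tab2$rate, tab$rate)

  # splitting a census row into two that preserve the total changes nothing
  cen_split <- gen$census
  i <- which(cen_split$living_count >= 2)[1]
  extra <- cen_split[i, ]
  extra$living_count <- 1
  cen_split$living_count[i] <- cen_split$living_count[i] - 1
  tab3 <- suppressWarnings(estimate_rates(gen$survey, rbind(cen_split, extra)))
  expect_equal(tab3$rate, tab$rate)
})

test_that("adding a killed tree never decreases a cell's rate", {
  gen <- gen_strike_survey(n_strikes = 30, seed = 8)
  tab <- suppressWarnings(estimate_rates(gen$survey, gen$census))
  sid <- filter_strikes(gen$survey)$neighbour[1]
  day <- select_survey(gen$survey[gen$survey$strike_id == sid, ])
  # census must actually have headroom in the target cell
  cell <- gen$census[gen$census$strike_id == sid & gen$census$zone == "z0_10" &
                       gen$census$size_class == "medium", ]
  stopifnot(cell$living_count > 0)
  extra <- survey_row(sid, "extra", 45, "z0_10", TRUE, survey_day = day)
  tab2 <- suppressWarnings(estimate_rates(rbind(gen$survey, extra), gen$census))
  expect_gt(rate_lookup(tab2, "medium", "z0_10"),
            rate_lookup(tab, "medium", "z0_10") - 1e-12)
  others <- !(tab$size_class == "medium" & tab$zone == "z0_10")
  expect_equal(tab2$rate[others], tab$rate[others])
})

test_that("estimation recovers known synthetic rates within binomial CIs", {
  truth <- synthetic_rate_table()
  gen <- gen_strike_survey(list(rate_table = truth), n_strikes = 400,
                           seed = 123)
  est <- suppressWarnings(estimate_rates(gen$survey, gen$census))
  rings <- zone_names(include_direct = FALSE)
  checked <- 0
  ok <- 0
  for (s in size_class_names()) for (z in rings) {
    i <- which(est$size_class == s & est$zone == z)
    n <- est$living[i]
    if (n < 30) next
    p_true <- rate_lookup(truth, s, z)
    ci <- p_true + c(-1, 1) * 1.96 * sqrt(p_true * (1 - p_true) / n)
    checked <- checked + 1
    ok <- ok + (est$rate[i] >= ci[1] && est$rate[i] <= ci[2])
  }
  expect_gte(checked, 20)
  expect_gte(ok / checked, 0.9)
})

test_that("per-strike kill means follow the direct/neighbour scoping", {
  sv <- rbind(
    # two in-plot, unambiguous strikes
    survey_row("A", "a1", 70, "direct", TRUE),
    survey_row("A", paste0("a", 2:4), c(15, 35, 5), "z0_10", TRUE),
    survey_row("B", "b1", 65, "direct", FALSE),
    survey_row("B", "b2", 12, "z10_20", TRUE),
    # an out-of-plot strike: direct scope only
    survey_row("C", "c1", 80, "direct", TRUE, in_plot = FALSE)
  )
  res <- trees_killed_per_strike(sv, min_diameter_cm = 10)
  # direct kills >= 10 cm: A, C -> 2 of 3 strikes; neighbours: A(2) + B(1)
  expect_equal(res$n_direct, 3)
  expect_equal(res$n_neighbour, 2)
  expect_equal(res$total, 2 / 3 + 3 / 2)
  expect_equal(unname(res$per_size[c("small", "medium", "large")]),
               c(2 / 2, 1 / 2, 2 / 3))
  # the tiny 5 cm death is excluded by the threshold
  expect_equal(unname(res$per_size["tiny"]), 0)

  # widening the neighbour scope to all strikes dilutes the mean
  res_all <- trees_killed_per_strike(sv, min_diameter_cm = 10,
                                     neighbour_scope = "all")
  expect_equal(res_all$n_neighbour, 3)
  expect_lt(res_all$total, res$total)

  expect_error(trees_killed_per_strike(sv[sv$strike_id == "Z", ]),
               "missing columns|empty")
})

test_that("zero-death surveys give zero kills per strike", {
  sv <- rbind(survey_row("A", "a1", 70, "direct", FALSE),
              survey_row("B", "b1", 30, "direct", FALSE))
  res <- trees_killed_per_strike(sv)
  expect_equal(res$total, 0)
})

test_that("bootstrap quantiles bracket the point estimate", {
  gen <- gen_strike_survey(n_strikes = 25, seed = 3)
  bs <- suppressWarnings(bootstrap_rates(gen$survey, gen$census, n_boot = 30,
                                         seed = 2))
  i <- which(bs$size_class == "small" & bs$zone == "z0_10")
  expect_lte(bs$`q0.025`[i], bs$rate[i] + 1e-9)
  expect_gte(bs$`q0.975`[i], bs$rate[i] - 1e-9)
})

test_that("survey and census CSVs validate on read", {
  gen <- gen_strike_survey(n_strikes = 5, seed = 1)
  sf <- withr::local_tempfile(fileext = ".csv")
  cf <- withr::local_tempfile(fileext = ".csv")
  write.csv(gen$survey, sf, row.names = FALSE)
  write.csv(gen$census, cf, row.names = FALSE)
  expect_equal(nrow(read_strike_survey_csv(sf)), nrow(gen$survey))
  expect_equal(nrow(read_census_csv(cf)), nrow(gen$census))
  expect_error(read_strike_survey_csv(cf), "missing columns")
  expect_error(read_census_csv(sf), "missing columns")
})
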