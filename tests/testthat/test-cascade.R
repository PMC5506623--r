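test_that("cases are population at risk times incidence", {
  row <- single_setting_row(condition = "diarrhea",
                            under5_population = 100000, incidence = 3.3)
  expect_equal(cases_for_year(row), 330000, tolerance = 1e-12)
  row2 <- single_setting_row(condition = "pph", pregnancies = 50000,
                             incidence = 0.05)
  expect_equal(cases_for_year(row2), 2500, tolerance = 1e-12)
  expect_identical(cases_for_year(single_setting_row(incidence = 0)), 0)
  bad <- single_setting_row()
  bad$condition_id <- "gout"
  expect_error(cases_for_year(bad), "target population")
})

test_that("expected deaths split cases by treated and untreated CFRs", {
  expect_equal(expected_deaths(100, 0.6, 0.05, 0.2), 11.0, tolerance = 1e-12)
  expect_equal(expected_deaths(100, 0, 0.05, 0.2), 20)
  # equal CFRs make treatment status irrelevant
  for (tf in c(0, 0.3, 1)) {
    expect_equal(expected_deaths(100, tf, 0.1, 0.1), 10, tolerance = 1e-12)
  }
})

test_that("the baseline cascade reproduces the single-setting hand result", {
  tbl <- single_setting_table()
  bl <- run_baseline(tbl, "pneumonia")
  home_2015 <- bl[bl$setting == "home" & bl$year == 2015, ]
  expect_equal(home_2015$cases, 1000, tolerance = 1e-12)
  expect_equal(home_2015$treated_effectively, 400, tolerance = 1e-12)
  expect_equal(home_2015$deaths, 400 * 0.01 + 600 * 0.1, tolerance = 1e-12)
})

test_that("zero coverage leaves deaths at the mix-weighted untreated CFR", {
  tbl <- single_setting_table(
    setting_mix_home = 0.6, setting_mix_clinic = 0.3, setting_mix_hospital = 0.1,
    baseline_coverage_home = 0, baseline_coverage_clinic = 0,
    baseline_coverage_hospital = 0,
    cfr_untreated_home = 0.1, cfr_untreated_clinic = 0.05,
    cfr_untreated_hospital = 0.02
  )
  bl <- run_baseline(tbl, "pneumonia")
  per_year <- cascade_totals(bl)
  expect_equal(per_year$deaths,
               rep(1000 * (0.6 * 0.1 + 0.3 * 0.05 + 0.1 * 0.02), 16),
               tolerance = 1e-12)
})

test_that("missing horizon years are reported by country and year", {
  tbl <- single_setting_table()
  tbl <- tbl[tbl$year != 2020, ]
  expect_error(run_baseline(tbl, "pneumonia"), "SAA.*2020")
})

test_that("null innovations and pre-launch years reproduce the baseline exactly", {
  tbl <- generate_country_inputs(
    synth_config(seed = 21, n_countries = 2, conditions = "diarrhea"))
  bl <- run_baseline(tbl, "diarrhea")
  sc <- run_scenario(tbl, "diarrhea", null_innovation("diarrhea"))
  expect_identical(bl$deaths, sc$deaths)

  late <- builtin_preset("water_chlorinator")
  late$launch_year <- 2024L
  sc_late <- run_scenario(tbl, "diarrhea", late)
  pre <- sc_late$year < 2024
  expect_identical(bl$deaths[pre], sc_late$deaths[pre])
  expect_lt(sum(sc_late$deaths[!pre]), sum(bl$deaths[!pre]))
})

test_that("chlorhexidine multiplies home deaths by 1 - 0.55 x 0.23 at peak", {
  tbl <- single_setting_table(condition = "neonatal_sepsis", incidence = 0.05,
                              cfr_treated_home = 0.05, cfr_untreated_home = 0.2)
  bl <- run_baseline(tbl, "neonatal_sepsis")
  sc <- run_scenario(tbl, "neonatal_sepsis", builtin_preset("chlorhexidine"))
  at_peak <- sc$year >= 2019 & sc$setting == "home"  # 2015 launch + 5y ramp
  expect_equal(sc$deaths[at_peak] / bl$deaths[at_peak],
               rep(1 - 0.55 * 0.23, sum(at_peak)), tolerance = 1e-12)
})

test_that("every scenario conserves cases and keeps quantities non-negative", {
  tbl <- generate_country_inputs(synth_config(seed = 31, n_countries = 2))
  for (nm in preset_names()) {
    spec <- builtin_preset(nm)
    sc <- suppressWarnings(run_scenario(tbl, spec$condition_id, spec))
    expect_equal(sc$treated_effectively + sc$untreated, sc$cases,
                 tolerance = 1e-9, label = nm)
    expect_true(all(sc$deaths <= sc$cases + 1e-9), label = nm)
    numeric_cols <- c("cases", "treated_effectively", "untreated", "deaths",
                      "prevented_cases", "additional_treatments",
                      "false_positive_treatments", "innovation_uses",
                      "innovation_units_used")
    for (col in numeric_cols) {
      expect_true(all(sc[[col]] >= -1e-12), label = paste(nm, col))
    }
    # totals equal sums over settings
    totals <- cascade_totals(sc)
    expect_equal(sum(totals$deaths), sum(sc$deaths), tolerance = 1e-9)
  }
})

test_that("incremental lives saved is additive and guards its inputs", {
  tbl <- generate_country_inputs(
    synth_config(seed = 41, n_countries = 2, conditions = "diarrhea"))
  bl <- run_baseline(tbl, "diarrhea")
  fc <- incremental_lives_saved(bl, bl)
  expect_identical(unique(fc$by_year$lives_saved), 0)
  sc <- run_scenario(tbl, "diarrhea", builtin_preset("water_chlorinator"))
  fc2 <- incremental_lives_saved(bl, sc)
  expect_equal(fc2$cumulative_lives_saved, sum(fc2$by_year$lives_saved),
               tolerance = 1e-9)
  expect_error(incremental_lives_saved(bl, sc[-1, ]), "same roster")
})

test_that("a harmful configuration warns but is still reported", {
  # replace the comparator with a much less effective product
  tbl <- single_setting_table(condition = "pph", incidence = 0.05)
  worse <- innovation_spec(
    "worse", "pph", "coverage_expansion", launch_year = 2015, unit_cost = 1,
    peak_coverage = c(home = 0.5), effectiveness = c(home = 0.1),
    market_behavior = "replace"
  )
  bl <- run_baseline(tbl, "pph")
  sc <- run_scenario(tbl, "pph", worse)
  expect_warning(fc <- incremental_lives_saved(bl, sc), "[Nn]egative")
  expect_lt(fc$cumulative_lives_saved, 0)
})
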