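test_that("a zero-coverage innovation costs nothing", {
  tbl <- generate_country_inputs(
    synth_config(seed = 13, n_countries = 1, conditions = "diarrhea"))
  fc <- run_forecast(tbl, NULL, condition = "diarrhea")
  expect_identical(unique(fc$by_year$lives_saved), 0)
  expect_identical(unique(fc$by_year$incremental_cost), 0)
  expect_identical(fc$cumulative_incremental_cost, 0)
})

test_that("device units are purchased by ceiling division of covered persons", {
  # 4000 eligible-weighted persons x 0.5 eligibility x 25% peak = 500 covered;
  # one 1000-person chlorinator at $70
  tbl <- single_setting_table(condition = "diarrhea",
                              under5_population = 4000, incidence = 1,
                              eligible_fraction = 0.5)
  spec <- builtin_preset("water_chlorinator")
  bl <- run_baseline(tbl, "diarrhea")
  sc <- run_scenario(tbl, "diarrhea", spec)
  costs <- incremental_cost(bl, sc, spec)
  at_peak <- costs$year >= 2019
  expect_equal(costs$innovation_cost[at_peak], rep(70, sum(at_peak)),
               tolerance = 1e-12)
  uses_2019 <- sum(sc$innovation_uses[sc$year == 2019])
  expect_equal(uses_2019, 500, tolerance = 1e-9)
})

test_that("reported costs equal the four-term decomposition recomputed independently", {
  tbl <- generate_country_inputs(synth_config(seed = 55, n_countries = 2))
  for (nm in c("water_chlorinator", "pulse_oximeter", "ubt")) {
    spec <- builtin_preset(nm)
    bl <- run_baseline(tbl, spec$condition_id)
    sc <- run_scenario(tbl, spec$condition_id, spec)
    costs <- incremental_cost(bl, sc, spec)

    # independent recomputation from the cascade rows, base R only
    df <- as.data.frame(sc)
    innovation <- tapply(df$innovation_units_used, df$year, sum) * spec$unit_cost
    downstream <- tapply((df$additional_treatments +
                            df$false_positive_treatments) *
                           df$treatment_cost_per_case, df$year, sum)
    averted <- tapply(df$prevented_cases * df$treatment_cost_per_case,
                      df$year, sum)
    expected <- as.numeric(innovation + downstream - averted)
    expect_equal(costs$incremental_cost, expected, tolerance = 1e-9,
                 label = nm)
  }
})

test_that("introduction costs are booked once per country in the launch year", {
  tbl <- generate_country_inputs(
    synth_config(seed = 6, n_countries = 3, conditions = "pph"))
  spec <- builtin_preset("oxytocin_new_formulation")
  spec$introduction_cost <- 10000
  fc <- run_forecast(tbl, spec)
  intro <- fc$by_year$introduction_cost
  expect_equal(sum(intro), 3 * 10000)
  expect_equal(fc$by_year$year[intro > 0], 2022)
})

test_that("lives saved add over countries run one at a time", {
  tbl <- generate_country_inputs(
    synth_config(seed = 77, n_countries = 3, conditions = "neonatal_sepsis"))
  spec <- builtin_preset("chlorhexidine")
  whole <- run_forecast(tbl, spec)
  parts <- vapply(unique(tbl$country_code), function(cc) {
    run_forecast(tbl[tbl$country_code == cc, ], spec)$cumulative_lives_saved
  }, numeric(1))
  expect_equal(whole$cumulative_lives_saved, sum(parts), tolerance = 1e-9)
})

test_that("forecast outputs and manifests are written and reproducible", {
  tbl <- generate_country_inputs(
    synth_config(seed = 2, n_countries = 2, conditions = "pneumonia"))
  out <- withr::local_tempdir()
  fc1 <- run_forecast(tbl, "rr_monitor", out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("forecast.csv", "summary.json", "manifest.json")))))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(manifest$innovation_id, "rr_monitor")
  fc2 <- run_forecast(tbl, "rr_monitor")
  expect_identical(fc1$metadata$config_hash, fc2$metadata$config_hash)
  expect_identical(fc1$by_year, fc2$by_year)

  csv <- utils::read.csv(file.path(out, "forecast.csv"))
  expect_equal(nrow(csv), 2 * 16)
  expect_equal(sum(csv$lives_saved), fc1$cumulative_lives_saved,
               tolerance = 1e-9)
})

test_that("sensitivity runs are full re-runs anchored to a central case", {
  tbl <- generate_country_inputs(
    synth_config(seed = 10, n_countries = 2, conditions = "diarrhea"))
  sens0 <- one_at_a_time_sensitivity(tbl, "water_chlorinator",
                                     parameters = "peak_coverage", delta = 0)
  expect_equal(sens0$cumulative_lives_saved,
               rep(sens0$cumulative_lives_saved[1], nrow(sens0)),
               tolerance = 1e-12)
  expect_error(
    one_at_a_time_sensitivity(tbl, "water_chlorinator",
                              parameters = "unit_cost"),
    "cost_bounds"
  )
  expect_error(
    one_at_a_time_sensitivity(tbl, "water_chlorinator",
                              parameters = "price_of_tea"),
    "Unknown sensitivity parameter"
  )
})
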