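test_that("country tables load from CSV with one record per input row, sorted", {
  tbl <- generate_country_inputs(
    synth_config(seed = 5, n_countries = 2, conditions = "diarrhea"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_country_table(tbl, path)
  loaded <- load_country_table(path)
  expect_equal(nrow(loaded), 2 * 16)
  expect_identical(
    order(loaded$country_code, loaded$condition_id, loaded$year),
    seq_len(nrow(loaded))
  )
})

test_that("CSV and JSON round-trips are lossless", {
  tbl <- generate_country_inputs(
    synth_config(seed = 8, n_countries = 2, conditions = c("pph", "diarrhea")))
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_country_table(tbl, path)
    loaded <- load_country_table(path)
    expect_identical(as.data.frame(loaded), as.data.frame(tbl), label = ext)
  }
})

test_that("schema errors name the offending column or row", {
  tbl <- generate_country_inputs(synth_config(seed = 1, n_countries = 1,
                                              conditions = "pph"))
  path <- withr::local_tempfile(fileext = ".csv")
  no_col <- as.data.frame(tbl)
  no_col$incidence <- NULL
  utils::write.csv(no_col, path, row.names = FALSE)
  expect_error(load_country_table(path), "incidence")

  broken <- as.data.frame(tbl)
  broken$incidence[3] <- "not-a-number"
  utils::write.csv(broken, path, row.names = FALSE)
  expect_error(load_country_table(path), "incidence.*3")
})

test_that("validation reports every invariant violation with a row locator", {
  tbl <- generate_country_inputs(
    synth_config(seed = 3, n_countries = 2, conditions = "pneumonia"))
  expect_true(validate_inputs(tbl)$valid)

  bad <- tbl
  # one row, one violation: treated CFR above untreated
  bad$cfr_treated_home[4] <- 0.3
  bad$cfr_untreated_home[4] <- 0.2
  report <- validate_inputs(bad)
  expect_false(report$valid)
  expect_equal(nrow(report$errors), 1L)
  expect_equal(report$errors$row, 4L)
  expect_match(report$errors$rule, "cfr_order")

  # same row, second violation: setting mix that sums to 0.9
  bad$setting_mix_home[4] <- 0.5
  bad$setting_mix_clinic[4] <- 0.3
  bad$setting_mix_hospital[4] <- 0.1
  report2 <- validate_inputs(bad)
  expect_equal(nrow(report2$errors), 2L)
  expect_setequal(report2$errors$row, 4L)
})

test_that("violations are data, not exceptions, but engines refuse them", {
  bad <- single_setting_table(setting_mix_home = 0.5, setting_mix_clinic = 0.3,
                              setting_mix_hospital = 0.1)
  expect_no_error(report <- validate_inputs(bad))
  expect_false(report$valid)
  expect_error(run_baseline(bad, "pneumonia"), "validation")
})

test_that("innovation specs round-trip through JSON and YAML", {
  spec <- builtin_preset("water_chlorinator")
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_innovation_spec(spec, path)
    back <- read_innovation_spec(path)
    expect_equal(back$peak_coverage, spec$peak_coverage, label = ext)
    expect_equal(back$effectiveness, spec$effectiveness, label = ext)
    expect_identical(back$mechanism, spec$mechanism, label = ext)
    expect_identical(back$units_per_person_covered,
                     spec$units_per_person_covered, label = ext)
  }
})

test_that("malformed innovation specs are rejected with clear messages", {
  expect_error(
    innovation_spec("x", "pph", "nonsense", 2015, 1,
                    peak_coverage = c(home = 0.5),
                    effectiveness = c(home = 0.5)),
    "mechanism"
  )
  expect_error(
    innovation_spec("x", "pph", "coverage_expansion", 2015, -1,
                    peak_coverage = c(home = 0.5),
                    effectiveness = c(home = 0.5)),
    "unit_cost"
  )
  expect_error(
    innovation_spec("x", "pph", "coverage_expansion", 2015, 1,
                    peak_coverage = c(home = 1.5),
                    effectiveness = c(home = 0.5)),
    "peak_coverage"
  )
  expect_error(
    innovation_spec("x", "pph", "coverage_expansion", 2015, 1, ramp_years = 0,
                    peak_coverage = c(home = 0.5),
                    effectiveness = c(home = 0.5)),
    "ramp_years"
  )
})

test_that("unknown presets list the available ones", {
  expect_error(builtin_preset("warp_drive"), "oxytocin_new_formulation")
  expect_setequal(preset_names(), preset_transcription()$name)
})

test_that("chlorhexidine roster adjustment adds and removes the named countries", {
  roster <- c("IDN", "NGA", "LKA", "BGD")
  adjusted <- adjust_roster_chlorhexidine(roster)
  expect_true(all(c("AGO", "AFG", "DJI", "NGA", "BGD") %in% adjusted))
  expect_false(any(c("IDN", "LKA", "BTN", "PRK") %in% adjusted))
})
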