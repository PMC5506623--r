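# Shared fixtures: built in code, no files on disk.

# One country-table row with a single active setting (home by default),
# overridable field by field.
single_setting_row <- function(condition = "pneumonia", year = 2015L, ...) {
  row <- tibble::tibble(
    country_code = "SAA", year = as.integer(year), condition_id = condition,
    live_births = 1000, neonates = 1000, under5_population = 1000,
    pregnancies = 1000,
    incidence = 1,
    setting_mix_home = 1, setting_mix_clinic = 0, setting_mix_hospital = 0,
    baseline_coverage_home = 0.5, baseline_coverage_clinic = 0,
    baseline_coverage_hospital = 0,
    baseline_effectiveness_home = 0.8, baseline_effectiveness_clinic = 0,
    baseline_effectiveness_hospital = 0,
    cfr_treated_home = 0.01, cfr_treated_clinic = 0.01,
    cfr_treated_hospital = 0.01,
    cfr_untreated_home = 0.1, cfr_untreated_clinic = 0.1,
    cfr_untreated_hospital = 0.1,
    treatment_cost_per_case_home = 2, treatment_cost_per_case_clinic = 10,
    treatment_cost_per_case_hospital = 50,
    eligible_fraction = 1
  )
  overrides <- list(...)
  for (nm in names(overrides)) row[[nm]] <- overrides[[nm]]
  row
}

# Full-horizon single-setting table for one country (constant inputs).
single_setting_table <- function(condition = "pneumonia", ...,
                                 years = 2015:2030) {
  dplyr::bind_rows(lapply(years, function(y) {
    single_setting_row(condition = condition, year = y, ...)
  })) |> as_country_table()
}

# Field-for-field transcription of the eight shipped innovation parameter
# sets (launch year, unit cost, per-setting effectiveness and peak coverage,
# mechanism semantics). Tests assert presets against this table.
preset_transcription <- function() {
  tibble::tribble(
    ~name, ~condition, ~mechanism, ~launch, ~cost,
    ~eff_home, ~eff_clinic, ~eff_hospital,
    ~peak_home, ~peak_clinic, ~peak_hospital,
    ~market, ~upp, ~filter,
    "oxytocin_new_formulation", "pph", "coverage_expansion", 2022L, 0.50,
    0.40, 0.45, 0.45, 0.25, 0.20, 0.10, "expand", 1, NA,
    "ubt", "pph", "second_line_treatment", 2015L, 5.0,
    NA, 0.85, 0.85, NA, 0.50, 0.75, "expand", 1, NA,
    "odon", "obstructed_labor", "coverage_expansion", 2018L, 25,
    NA, 0.72, 0.81, NA, 0.40, NA, "expand", 1, NA,
    "chlorhexidine", "neonatal_sepsis", "mortality_reduction", 2015L, 0.36,
    0.23, NA, NA, 0.55, NA, NA, "expand", 1, "home_births",
    "diarrhea_treatment", "diarrhea", "adherence_boost", 2018L, 0.50,
    0.15, NA, NA, 0.80, NA, NA, "expand", 1, NA,
    "water_chlorinator", "diarrhea", "incidence_reduction", 2015L, 70,
    0.84, NA, NA, 0.25, NA, NA, "expand", 1000, "community_water",
    "pulse_oximeter", "pneumonia", "diagnostic_improvement", 2015L, 40,
    NA, 0.85, 0.85, NA, 0.70, 0.80, "expand", 1000, NA,
    "rr_monitor", "pneumonia", "diagnostic_improvement", 2015L, 50,
    NA, 0.80, 0.80, NA, 0.50, 0.60, "expand", 1000, NA
  )
}

# A spec exercising `mechanism` with scalable peak/effectiveness, placed in
# that mechanism's natural settings.
spec_for_mechanism <- function(mechanism, peak, eff, launch = 2015L,
                               condition = NULL) {
  settings_of <- list(
    incidence_reduction = "home",
    mortality_reduction = "home",
    coverage_expansion = c("home", "clinic", "hospital"),
    second_line_treatment = c("clinic", "hospital"),
    adherence_boost = "home",
    diagnostic_improvement = c("clinic", "hospital")
  )
  condition_of <- list(
    incidence_reduction = "diarrhea", mortality_reduction = "neonatal_sepsis",
    coverage_expansion = "pph", second_line_treatment = "pph",
    adherence_boost = "diarrhea", diagnostic_improvement = "pneumonia"
  )
  active <- settings_of[[mechanism]]
  vec <- function(v) {
    out <- stats::setNames(rep(NA_real_, 3), setting_ids())
    out[active] <- v
    out
  }
  innovation_spec(
    innovation_id = paste0("test_", mechanism),
    condition_id = condition %||% condition_of[[mechanism]],
    mechanism = mechanism,
    launch_year = launch, unit_cost = 1,
    peak_coverage = vec(peak), effectiveness = vec(eff)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cumulative lives saved of `spec` on `tbl` without the costing layer.
lives_saved_of <- function(tbl, spec, config = model_config()) {
  bl <- run_baseline(tbl, spec$condition_id, config)
  sc <- suppressWarnings(run_scenario(tbl, spec$condition_id, spec, config))
  sum(bl$deaths) - sum(sc$deaths)
}

# The preset that exercises each mechanism class.
mechanism_presets <- c(
  incidence_reduction = "water_chlorinator",
  mortality_reduction = "chlorhexidine",
  coverage_expansion = "oxytocin_new_formulation",
  second_line_treatment = "ubt",
  adherence_boost = "diarrhea_treatment",
  diagnostic_improvement = "pulse_oximeter"
)
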