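#' Expected condition cases in a country-year
#'
#' Cases are the product of the condition's population at risk and its
#' incidence: pregnancies for postpartum hemorrhage and obstructed labor,
#' neonates for neonatal sepsis, children under five for diarrhea and
#' pneumonia. For diarrhea, incidence is episodes per child-year and the
#' result counts episodes, so it may exceed the population.
#'
#' @param inputs One or more country-table rows.
#' @return Numeric vector of expected cases (real-valued expectations, one
#'   per row).
#' @export
#' @examples
#' tbl <- generate_country_inputs(synth_config(seed = 1, n_countries = 1))
#' cases_for_year(tbl[1, ])
cases_for_year <- function(inputs) {
  df <- tibble::as_tibble(inputs)
  field <- target_population_field(df$condition_id)
  pop <- vapply(seq_len(nrow(df)), function(i) df[[field[i]]][i], numeric(1))
  pop * df$incidence
}

#' Expected deaths among a pool of cases
#'
#' The cascade's terminal step: a case fatality rate is applied separately to
#' effectively treated and to untreated (or ineffectively treated) cases,
#' `deaths = cases * (treated_frac * cfr_treated + (1 - treated_frac) *
#' cfr_untreated)`.
#'
#' @param cases Case count (real-valued expectation).
#' @param treated_frac Fraction of cases effectively treated.
#' @param cfr_treated Deaths per effectively treated case.
#' @param cfr_untreated Deaths per untreated case.
#' @return Expected deaths (vectorized).
#' @export
#' @examples
#' expected_deaths(100, treated_frac = 0.6, cfr_treated = 0.05,
#'                 cfr_untreated = 0.2)
expected_deaths <- function(cases, treated_frac, cfr_treated, cfr_untreated) {
  check_fractions(treated_frac = treated_frac, cfr_treated = cfr_treated,
                  cfr_untreated = cfr_untreated)
  stopifnot(all(cases >= 0))
  cases * (treated_frac * cfr_treated + (1 - treated_frac) * cfr_untreated)
}

# Long-format cascade frame: one row per (country, year, setting) with the
# baseline inputs unpacked. Shared by run_baseline and run_scenario.
cascade_long <- function(records, condition, config) {
  df <- tibble::as_tibble(records)
  df <- df[df$condition_id == condition, , drop = FALSE]
  if (nrow(df) == 0L) {
    abort(sprintf("No rows for condition '%s' in the country table.", condition))
  }
  assert_valid_inputs(df, horizon = config$horizon)
  years <- seq(config$horizon[1], config$horizon[2])
  gaps <- df |>
    dplyr::group_by(.data$country_code) |>
    dplyr::summarise(missing = list(setdiff(years, .data$year)), .groups = "drop") |>
    dplyr::filter(lengths(.data$missing) > 0)
  if (nrow(gaps) > 0) {
    msg <- paste(vapply(seq_len(nrow(gaps)), function(i) {
      sprintf("%s: %s", gaps$country_code[i],
              paste(gaps$missing[[i]], collapse = ", "))
    }, character(1)), collapse = "; ")
    abort(sprintf("Country table has missing years in the horizon — %s.", msg))
  }

  field <- target_population_field(condition)
  purrr::map_dfr(.settings, function(s) {
    tibble::tibble(
      country_code = df$country_code,
      year = df$year,
      condition_id = condition,
      setting = s,
      pop_at_risk = df[[field]],
      incidence = df$incidence,
      mix = df[[paste0("setting_mix_", s)]],
      base_cov = df[[paste0("baseline_coverage_", s)]],
      base_eff = df[[paste0("baseline_effectiveness_", s)]],
      cfr_t = df[[paste0("cfr_treated_", s)]],
      cfr_u = df[[paste0("cfr_untreated_", s)]],
      cost_case = df[[paste0("treatment_cost_per_case_", s)]],
      eligible = df$eligible_fraction
    )
  }) |>
    dplyr::arrange(.data$country_code, .data$year,
                   factor(.data$setting, levels = .settings))
}

finish_cascade <- function(long, scenario_label) {
  out <- tibble::tibble(
    country_code = long$country_code,
    year = long$year,
    condition_id = long$condition_id,
    setting = long$setting,
    cases = unname(long$cases),
    treated_effectively = unname(long$cases * long$te_frac),
    untreated = unname(long$cases * (1 - long$te_frac)),
    deaths = unname(expected_deaths(long$cases, long$te_frac,
                                    long$cfr_t, long$cfr_u)),
    prevented_cases = long$prevented_cases,
    additional_treatments = long$additional_treatments,
    false_positive_treatments = long$false_positive_treatments,
    innovation_uses = long$innovation_uses,
    innovation_units_used = long$innovation_units_used,
    treatment_cost_per_case = long$cost_case,
    scenario = scenario_label
  )
  class(out) <- c("cascade_result", class(out))
  out
}

#' Run the baseline (standard-of-care) cascade
#'
#' For every country-year of one condition: expected cases are split across
#' the home/clinic/hospital settings by the presentation mix; within each
#' setting the fraction `baseline_coverage * baseline_effectiveness` is
#' effectively treated; treated and untreated case fatality rates then give
#' expected deaths. This is the comparator against which every innovation is
#' evaluated.
#'
#' @param records A `country_table`.
#' @param condition One of [condition_ids()].
#' @param config A [model_config()].
#' @return A `cascade_result` tibble, one row per (country, year, setting),
#'   with columns `cases`, `treated_effectively`, `untreated`, `deaths`, and
#'   zeroed innovation accounting columns.
#' @export
run_baseline <- function(records, condition, config = model_config()) {
  long <- cascade_long(records, condition, config)
  long$cases <- long$pop_at_risk * long$incidence * long$mix
  long$te_frac <- long$base_cov * long$base_eff
  long$prevented_cases <- 0
  long$additional_treatments <- 0
  long$false_positive_treatments <- 0
  long$innovation_uses <- 0
  long$innovation_units_used <- 0
  finish_cascade(long, "baseline")
}

#' Run the cascade with one innovation inserted
#'
#' Identical to [run_baseline()] except that the innovation's mechanism
#' transform is applied to the relevant cascade quantity in the settings the
#' innovation enters, with year-specific adoption from [coverage_at_year()].
#' Exactly one innovation is inserted per scenario; results for different
#' innovations against the same condition are not additive.
#'
#' @inheritParams run_baseline
#' @param innovation An [innovation_spec()] whose `condition_id` matches
#'   `condition`.
#' @return A `cascade_result` tibble with innovation accounting columns
#'   (`prevented_cases`, `additional_treatments`,
#'   `false_positive_treatments`, `innovation_uses`,
#'   `innovation_units_used`) filled in.
#' @export
run_scenario <- function(records, condition, innovation,
                         config = model_config()) {
  stopifnot(inherits(innovation, "innovation_spec"))
  if (innovation$condition_id != condition) {
    abort(sprintf(
      "Innovation '%s' targets condition '%s', not '%s'.",
      innovation$innovation_id, innovation$condition_id, condition
    ))
  }
  long <- cascade_long(records, condition, config)
  n <- nrow(long)

  peak <- innovation$peak_coverage
  eff <- innovation$effectiveness
  active <- !is.na(peak)
  rampf <- ramp_fraction(innovation, long$year)
  cov_s <- unname(ifelse(active[long$setting], peak[long$setting], 0) * rampf)
  eff_s <- unname(ifelse(active[long$setting] & !is.na(eff[long$setting]),
                         eff[long$setting], 0))
  # Population-share eligibility gate: only filters tied to the
  # eligible_fraction column scale reach; structural gates (home births) are
  # already encoded in the per-setting peaks.
  gate <- innovation$eligible_population_filter
  elig <- if (!is.null(gate) && gate %in% c("community_water", "eligible_fraction")) {
    long$eligible
  } else {
    rep(1, n)
  }

  long$cases <- long$pop_at_risk * long$incidence * long$mix
  long$te_frac <- long$base_cov * long$base_eff
  long$prevented_cases <- 0
  long$additional_treatments <- 0
  long$false_positive_treatments <- 0
  long$innovation_uses <- 0

  mech <- innovation$mechanism
  if (mech == "incidence_reduction") {
    # Prevention acts on the whole eligible population before cases split by
    # presentation setting; the (single) specified setting carries adoption.
    lead <- names(which(active))[which.max(peak[active])]
    cov_pop <- unname(peak[lead]) * rampf
    eff_pop <- unname(eff[lead])
    mult <- 1 - elig * cov_pop * eff_pop
    base_cases <- long$cases
    long$cases <- base_cases * mult
    long$prevented_cases <- base_cases - long$cases
    long$innovation_uses <- ifelse(long$setting == lead,
                                   long$pop_at_risk * elig * cov_pop, 0)
  } else if (mech == "mortality_reduction") {
    m <- elig * cov_s * eff_s
    long$cfr_t <- long$cfr_t * (1 - m)
    long$cfr_u <- long$cfr_u * (1 - m)
    long$innovation_uses <- long$pop_at_risk * long$mix * elig * cov_s
  } else if (mech == "coverage_expansion") {
    cov_in <- elig * cov_s
    if (innovation$market_behavior == "expand" &&
        any(long$base_cov + cov_in > 1 + 1e-12)) {
      warn("Expanded treatment coverage exceeds 1 in some rows; clipping to 1.")
    }
    sh <- expansion_shares(long$base_cov, cov_in, innovation$market_behavior)
    long$te_frac <- sh$comparator * long$base_eff + sh$innovation * eff_s
    added <- pmax(0, sh$total - long$base_cov)
    long$additional_treatments <- long$cases * added
    long$innovation_uses <- long$cases * sh$innovation
  } else if (mech == "second_line_treatment") {
    pool_frac <- long$base_cov * (1 - long$base_eff)
    if (config$second_line_pool == "all_failures") {
      pool_frac <- pool_frac + (1 - long$base_cov)
    }
    failures <- long$cases * pool_frac
    rescued <- apply_second_line(failures, elig * cov_s, eff_s)
    long$te_frac <- long$te_frac +
      ifelse(long$cases > 0, rescued / long$cases, 0)
    long$additional_treatments <- failures * elig * cov_s
    long$innovation_uses <- failures * elig * cov_s
  } else if (mech == "adherence_boost") {
    boost <- eff_s * rampf  # eff_s holds percentage points at peak
    boosted <- long$base_cov + ifelse(active[long$setting], boost * elig, 0)
    if (any(boosted > 1 + 1e-12)) {
      warn("Boosted coverage exceeds 1 in some rows; clipping to 1.")
    }
    boosted <- pmin(1, boosted)
    long$additional_treatments <- long$cases * (boosted - long$base_cov)
    long$te_frac <- boosted * long$base_eff
    long$innovation_uses <- long$cases * cov_s * elig
  } else if (mech == "diagnostic_improvement") {
    # Replace-if-better: the covered share is diagnosed with the device's
    # detection probability when it beats the standard pathway.
    dtc <- innovation$downstream_treatment_coverage
    add_cov <- elig * cov_s * pmax(0, eff_s - long$base_cov) * dtc
    long$te_frac <- (long$base_cov + add_cov) * long$base_eff
    long$additional_treatments <- long$cases * add_cov
    noncases <- config$noncase_multiple * long$cases
    long$false_positive_treatments <- noncases * elig * cov_s *
      (1 - innovation$specificity) * dtc
    long$innovation_uses <- (long$cases + noncases) * elig * cov_s
  } else {
    abort(sprintf("Unknown mechanism '%s'.", mech))
  }

  long$te_frac <- pmin(1, pmax(0, long$te_frac))
  # Units purchased per country-year: ceiling of uses over persons-per-unit,
  # amortized over the device lifetime; booked on the first setting row so
  # totals remain sums over settings.
  units <- long |>
    dplyr::group_by(.data$country_code, .data$year) |>
    dplyr::mutate(
      uses_cy = sum(.data$innovation_uses),
      innovation_units_used = ifelse(
        .data$setting == .settings[1] & .data$uses_cy > 0,
        ceiling(.data$uses_cy / innovation$units_per_person_covered) /
          innovation$device_lifetime_years,
        0
      )
    ) |>
    dplyr::ungroup()
  long$innovation_units_used <- units$innovation_units_used
  finish_cascade(long, innovation$innovation_id)
}

#' Per-year totals of a cascade result
#'
#' @param result A `cascade_result`.
#' @return Tibble with one row per year: total cases, deaths, treatments,
#'   false positives, prevented cases, and innovation units.
#' @export
cascade_totals <- function(result) {
  result |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      cases = sum(.data$cases),
      treated_effectively = sum(.data$treated_effectively),
      untreated = sum(.data$untreated),
      deaths = sum(.data$deaths),
      prevented_cases = sum(.data$prevented_cases),
      additional_treatments = sum(.data$additional_treatments),
      false_positive_treatments = sum(.data$false_positive_treatments),
      innovation_units_used = sum(.data$innovation_units_used),
      .groups = "drop"
    )
}

#' Incremental lives saved between baseline and scenario
#'
#' Lives saved in a year are baseline deaths minus scenario deaths, summed
#' over the roster; the cumulative total sums over the horizon. Negative
#' values (a harmful configuration) are reported, not suppressed, with a
#' warning.
#'
#' @param baseline,scenario `cascade_result`s from [run_baseline()] and
#'   [run_scenario()] over the same roster, years, and condition.
#' @return A `forecast_result`: list with `by_year` (tibble of
#'   `baseline_deaths`, `scenario_deaths`, `lives_saved`, and cost columns
#'   filled by [incremental_cost()]), `cumulative_lives_saved`, and
#'   `metadata`.
#' @export
incremental_lives_saved <- function(baseline, scenario) {
  key <- function(x) paste(x$country_code, x$year, x$setting)
  if (nrow(baseline) != nrow(scenario) ||
      !identical(key(baseline), key(scenario)) ||
      !identical(unique(baseline$condition_id), unique(scenario$condition_id))) {
    abort("Baseline and scenario must cover the same roster, years, and condition.")
  }
  by_year <- dplyr::left_join(
    cascade_totals(baseline) |>
      dplyr::select("year", baseline_deaths = "deaths"),
    cascade_totals(scenario) |>
      dplyr::select("year", scenario_deaths = "deaths"),
    by = "year"
  ) |>
    dplyr::mutate(
      lives_saved = .data$baseline_deaths - .data$scenario_deaths,
      incremental_cost = NA_real_
    )
  if (any(by_year$lives_saved < -1e-9)) {
    warn("Negative lives saved in some years: the scenario increases deaths.")
  }
  structure(
    list(
      by_year = by_year,
      cumulative_lives_saved = sum(by_year$lives_saved),
      cumulative_incremental_cost = NA_real_,
      metadata = list(
        innovation_id = unique(scenario$scenario),
        condition_id = unique(scenario$condition_id),
        roster = sort(unique(baseline$country_code)),
        years = range(by_year$year)
      )
    ),
    class = "forecast_result"
  )
}

#' @export
print.forecast_result <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<forecast_result> %s (%s), %d countries, %d-%d\n",
              md$innovation_id, md$condition_id, length(md$roster),
              md$years[1], md$years[2]))
  cat(sprintf("  cumulative lives saved:      %.1f\n", x$cumulative_lives_saved))
  if (!is.na(x$cumulative_incremental_cost)) {
    cat(sprintf("  cumulative incremental cost: $%.0f\n",
                x$cumulative_incremental_cost))
    if (!is.null(x$cost_per_death_averted) && is.finite(x$cost_per_death_averted)) {
      cat(sprintf("  cost per death averted:      $%.0f\n",
                  x$cost_per_death_averted))
    }
  }
  invisible(x)
}
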