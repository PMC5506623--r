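#' Incremental cost of an innovation scenario
#'
#' Costs are undiscounted nominal USD by default, decomposed into four
#' terms per year:
#' innovation spend (units purchased by ceiling division of covered persons
#' or expected uses by `units_per_person_covered`, times `unit_cost`,
#' amortized over `device_lifetime_years`), a one-time per-country
#' introduction cost in the launch year, downstream treatment costs of
#' additionally treated cases (true and false positives), minus treatment
#' costs averted by prevented cases. Research-and-development and
#' economic-productivity costs are out of scope. Negative totals are cost
#' savings.
#'
#' @param baseline,scenario `cascade_result`s from the same roster/horizon.
#' @param innovation The [innovation_spec()] used for the scenario.
#' @param config A [model_config()].
#' @return Tibble with one row per year: `innovation_cost`,
#'   `introduction_cost`, `downstream_cost`, `averted_cost`,
#'   `incremental_cost`, plus a `cumulative` attribute-free total obtainable
#'   by summing `incremental_cost`.
#' @export
incremental_cost <- function(baseline, scenario, innovation,
                             config = model_config()) {
  stopifnot(inherits(innovation, "innovation_spec"))
  key <- function(x) paste(x$country_code, x$year, x$setting)
  if (!identical(key(baseline), key(scenario))) {
    abort("Baseline and scenario must cover the same roster and horizon.")
  }
  by_year <- scenario |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      innovation_cost = sum(.data$innovation_units_used) * innovation$unit_cost,
      downstream_cost = sum((.data$additional_treatments +
                               .data$false_positive_treatments) *
                              .data$treatment_cost_per_case),
      averted_cost = sum(.data$prevented_cases * .data$treatment_cost_per_case),
      .groups = "drop"
    )
  by_year$introduction_cost <- 0
  launches <- any(!is.na(innovation$peak_coverage) &
                    innovation$peak_coverage > 0) &&
    innovation$launch_year <= config$horizon[2]
  if (launches && innovation$introduction_cost > 0) {
    intro_year <- max(innovation$launch_year, config$horizon[1])
    n_countries <- length(unique(scenario$country_code))
    by_year$introduction_cost[by_year$year == intro_year] <-
      innovation$introduction_cost * n_countries
  }
  if (config$discount_rate > 0) {
    disc <- (1 + config$discount_rate)^(by_year$year - config$horizon[1])
    for (col in c("innovation_cost", "downstream_cost", "averted_cost",
                  "introduction_cost")) {
      by_year[[col]] <- by_year[[col]] / disc
    }
  }
  by_year$incremental_cost <- by_year$innovation_cost +
    by_year$introduction_cost + by_year$downstream_cost - by_year$averted_cost
  by_year[c("year", "innovation_cost", "introduction_cost",
            "downstream_cost", "averted_cost", "incremental_cost")]
}

#' Run a full incremental-impact forecast
#'
#' Composes [run_baseline()], [run_scenario()], [incremental_lives_saved()],
#' and [incremental_cost()] for one innovation over one roster and horizon.
#'
#' @param records A `country_table`, or a path readable by
#'   [load_country_table()].
#' @param innovation An [innovation_spec()], the name of a shipped preset
#'   (see [preset_names()]), or `NULL` for a null (no-innovation) run.
#' @param condition Required when `innovation` is `NULL`; otherwise taken
#'   from the spec.
#' @param config A [model_config()].
#' @param out_dir Optional directory; when given, writes `forecast.csv`
#'   (country-year rows), `summary.json`, and `manifest.json`.
#' @return A `forecast_result` with cost columns filled, the underlying
#'   `baseline` and `scenario` cascade tibbles, and a metadata manifest
#'   (innovation id, roster, horizon, config hash).
#' @export
#' @examples
#' tbl <- generate_country_inputs(
#'   synth_config(seed = 7, n_countries = 2, conditions = "diarrhea"))
#' run_forecast(tbl, "water_chlorinator")
run_forecast <- function(records, innovation = NULL, condition = NULL,
                         config = model_config(), out_dir = NULL) {
  if (is.character(records) && length(records) == 1L) {
    records <- load_country_table(records)
  }
  if (is.character(innovation)) innovation <- builtin_preset(innovation)
  if (is.null(innovation)) {
    if (is.null(condition)) {
      abort("Provide `condition` when running without an innovation.")
    }
    innovation <- null_innovation(condition)
  }
  condition <- innovation$condition_id

  baseline <- run_baseline(records, condition, config)
  scenario <- run_scenario(records, condition, innovation, config)
  result <- incremental_lives_saved(baseline, scenario)
  costs <- incremental_cost(baseline, scenario, innovation, config)
  result$by_year <- dplyr::left_join(
    dplyr::select(result$by_year, -"incremental_cost"), costs, by = "year")
  result$cumulative_incremental_cost <- sum(result$by_year$incremental_cost)
  result$cost_per_death_averted <-
    if (result$cumulative_lives_saved > 0) {
      result$cumulative_incremental_cost / result$cumulative_lives_saved
    } else {
      NA_real_
    }
  result$baseline <- baseline
  result$scenario <- scenario
  result$metadata$horizon <- config$horizon
  result$metadata$config <- unclass(config)
  result$metadata$package_version <- as.character(utils::packageVersion("mnchimpact"))
  result$metadata$config_hash <- rlang::hash(list(
    unclass(config), unclass(innovation)
  ))
  if (!is.null(out_dir)) write_forecast(result, out_dir)
  result
}

# Tidy country-year serialization of a forecast.
forecast_country_year <- function(result) {
  agg <- function(x, nm) {
    x |>
      dplyr::group_by(.data$country_code, .data$year) |>
      dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop") |>
      dplyr::rename(!!nm := "deaths")
  }
  dplyr::left_join(agg(result$baseline, "baseline_deaths"),
                   agg(result$scenario, "scenario_deaths"),
                   by = c("country_code", "year")) |>
    dplyr::mutate(lives_saved = .data$baseline_deaths - .data$scenario_deaths)
}

#' Write a forecast to disk
#'
#' Writes `forecast.csv` (one row per country-year with baseline deaths,
#' scenario deaths, and lives saved), `summary.json` (per-year and
#' cumulative lives saved and cost decomposition), and `manifest.json`
#' (innovation, roster, horizon, config hash, package version).
#'
#' @param result A `forecast_result` from [run_forecast()].
#' @param out_dir Output directory, created if absent.
#' @return `out_dir`, invisibly.
#' @export
write_forecast <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(forecast_country_year(result),
                   file.path(out_dir, "forecast.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      cumulative_lives_saved = result$cumulative_lives_saved,
      cumulative_incremental_cost = result$cumulative_incremental_cost,
      cost_per_death_averted = result$cost_per_death_averted,
      by_year = result$by_year
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows"
  )
  jsonlite::write_json(result$metadata, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

# Return a copy of a spec with one parameter perturbed; fractions are
# clipped to [0, 1] with a warning, never an error.
perturb_spec <- function(spec, parameter, delta = NULL, value = NULL) {
  out <- spec
  if (parameter %in% c("peak_coverage", "effectiveness")) {
    v <- out[[parameter]]
    idx <- !is.na(v)
    perturbed <- v[idx] + delta
    if (any(perturbed < -1e-12 | perturbed > 1 + 1e-12)) {
      warn(sprintf("Perturbed %s leaves [0, 1]; clipping.", parameter))
    }
    v[idx] <- pmin(1, pmax(0, perturbed))
    out[[parameter]] <- v
  } else if (parameter == "unit_cost") {
    out$unit_cost <- value
  } else {
    abort(sprintf("Cannot perturb parameter '%s'.", parameter))
  }
  validate_innovation_spec(out)
  out
}

#' One-at-a-time sensitivity analysis
#'
#' Each listed parameter is varied in isolation while all other inputs stay
#' at their central values, and the full forecast is re-run per perturbation.
#' Peak coverage and effectiveness move by plus and minus `delta` (default 5
#' percentage points) in every setting the innovation enters, clipped to
#' \[0, 1\]; innovation unit cost takes user-supplied lower and upper bounds.
#' Price does not influence coverage, so cost perturbations never change
#' death counts.
#'
#' @param records A `country_table` (or path).
#' @param innovation An [innovation_spec()] or preset name.
#' @param parameters Subset of `c("peak_coverage", "effectiveness",
#'   "unit_cost")`.
#' @param delta Percentage-point perturbation for coverage/effectiveness,
#'   default 0.05.
#' @param cost_bounds Length-2 numeric `c(lower, upper)` USD bounds;
#'   required when `"unit_cost"` is among `parameters`.
#' @param config A [model_config()].
#' @return A `sensitivity_result` tibble: one `central` row plus one row per
#'   perturbation, with cumulative lives saved, cumulative incremental cost,
#'   and deltas versus the central run. The central `forecast_result` is
#'   attached as attribute `central`.
#' @export
one_at_a_time_sensitivity <- function(records, innovation,
                                      parameters = c("peak_coverage",
                                                     "effectiveness"),
                                      delta = 0.05,
                                      cost_bounds = NULL,
                                      config = model_config()) {
  if (is.character(records) && length(records) == 1L) {
    records <- load_country_table(records)
  }
  if (is.character(innovation)) innovation <- builtin_preset(innovation)
  allowed <- c("peak_coverage", "effectiveness", "unit_cost")
  bad <- setdiff(parameters, allowed)
  if (length(bad) > 0) {
    abort(sprintf("Unknown sensitivity parameter(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  if ("unit_cost" %in% parameters && (is.null(cost_bounds) ||
                                      length(cost_bounds) != 2L)) {
    abort("Sensitivity on unit_cost needs `cost_bounds = c(lower, upper)`.")
  }

  central <- run_forecast(records, innovation, config = config)
  row <- function(parameter, perturbation, fc) {
    tibble::tibble(
      parameter = parameter,
      perturbation = perturbation,
      cumulative_lives_saved = fc$cumulative_lives_saved,
      cumulative_incremental_cost = fc$cumulative_incremental_cost,
      delta_lives_saved = fc$cumulative_lives_saved -
        central$cumulative_lives_saved,
      delta_incremental_cost = fc$cumulative_incremental_cost -
        central$cumulative_incremental_cost
    )
  }

  rows <- list(row("central", "central", central))
  for (p in intersect(c("peak_coverage", "effectiveness"), parameters)) {
    for (d in c(delta, -delta)) {
      spec_d <- perturb_spec(innovation, p, delta = d)
      fc <- run_forecast(records, spec_d, config = config)
      rows <- c(rows, list(row(p, sprintf("%+g", d), fc)))
    }
  }
  if ("unit_cost" %in% parameters) {
    for (i in 1:2) {
      spec_b <- perturb_spec(innovation, "unit_cost",
                             value = sort(cost_bounds)[i])
      fc <- run_forecast(records, spec_b, config = config)
      rows <- c(rows, list(row("unit_cost", c("lower", "upper")[i], fc)))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sensitivity_result", class(out))
  attr(out, "central") <- central
  out
}
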