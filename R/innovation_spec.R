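#' Innovation mechanism classes
#'
#' Each innovation perturbs the care cascade through exactly one mechanism:
#'
#' * `incidence_reduction` — prevents cases before they occur (e.g. water
#'   chlorination); `effectiveness` is the fractional incidence reduction
#'   among covered, eligible people.
#' * `mortality_reduction` — lowers the case fatality rate among covered
#'   cases (e.g. chlorhexidine cord care); `effectiveness` is the fractional
#'   CFR reduction at full coverage.
#' * `coverage_expansion` — brings treatment to cases the comparator does not
#'   reach (e.g. heat-stable oxytocin, Odon device); `effectiveness` is the
#'   innovation's own treatment effectiveness on the expanded share.
#' * `second_line_treatment` — rescues first-line treatment failures (e.g.
#'   uterine balloon tamponade after uterotonic failure).
#' * `adherence_boost` — raises coverage of an existing intervention by a
#'   fixed number of percentage points (e.g. new diarrhea treatments raising
#'   ORS coverage); `effectiveness` holds the percentage-point boost as a
#'   fraction (0.15 = 15 points). The boosted intervention keeps its own
#'   baseline effectiveness.
#' * `diagnostic_improvement` — raises the probability that a presenting case
#'   is diagnosed and referred to existing treatment (e.g. pulse oximeters,
#'   respiratory rate monitors); `effectiveness` is the device detection
#'   probability, and false positives among non-cases incur treatment costs
#'   without mortality benefit.
#'
#' @return Character vector of mechanism identifiers.
#' @export
mechanism_ids <- function() {
  c("incidence_reduction", "mortality_reduction", "coverage_expansion",
    "second_line_treatment", "adherence_boost", "diagnostic_improvement")
}

#' Construct an innovation specification
#'
#' An innovation specification captures everything the engine needs to insert
#' one innovation into the cascade: when it launches, how fast adoption ramps
#' (linearly over `ramp_years` to per-setting peak coverage), what it does
#' (`mechanism`), how well it works per setting, and what it costs.
#'
#' @param innovation_id Short identifier string.
#' @param condition_id One of [condition_ids()].
#' @param mechanism One of [mechanism_ids()].
#' @param launch_year Calendar year the innovation becomes available.
#' @param unit_cost USD per unit (dose, device, or product; see
#'   `units_per_person_covered`).
#' @param peak_coverage Named numeric (home/clinic/hospital) of peak adoption
#'   fractions; `NA` for settings the innovation does not enter.
#' @param effectiveness Named numeric per setting; mechanism-specific meaning
#'   (see [mechanism_ids()]). `NA` where not applicable.
#' @param ramp_years Years of linear ramp from launch to peak; the launch
#'   year itself carries `1/ramp_years` of peak.
#' @param units_per_person_covered Persons served per unit purchased
#'   (e.g. 1000 for a community batch chlorinator). Default 1.
#' @param introduction_cost One-time USD charge per country in the launch
#'   year. Default 0.
#' @param market_behavior `"expand"` (adds to comparator coverage, capped at
#'   1) or `"replace"` (takes over comparator market share). Only used by
#'   `coverage_expansion`.
#' @param eligible_population_filter Optional name of the population gate:
#'   `"community_water"` gates reach by the country table's
#'   `eligible_fraction` column; `"home_births"` is structural (encoded by
#'   home-only peak coverage). `NULL` means the whole target population is
#'   eligible.
#' @param specificity Diagnostic specificity (fraction of non-cases correctly
#'   ruled out); diagnostics only. Default 0.95.
#' @param device_lifetime_years Amortization horizon for durable devices;
#'   annual device cost is units-needed × `unit_cost` / lifetime. Default 1
#'   (units purchased each year).
#' @param downstream_treatment_coverage Fraction of positively diagnosed
#'   cases that go on to receive treatment (diagnostics only). Default 1.
#'
#' @return An object of class `innovation_spec` (a named list).
#' @export
#' @examples
#' innovation_spec(
#'   innovation_id = "demo_cord_antiseptic",
#'   condition_id = "neonatal_sepsis",
#'   mechanism = "mortality_reduction",
#'   launch_year = 2015, unit_cost = 0.36,
#'   peak_coverage = c(home = 0.55, clinic = NA, hospital = NA),
#'   effectiveness = c(home = 0.23, clinic = NA, hospital = NA)
#' )
innovation_spec <- function(innovation_id,
                            condition_id,
                            mechanism,
                            launch_year,
                            unit_cost,
                            peak_coverage,
                            effectiveness,
                            ramp_years = 5L,
                            units_per_person_covered = 1,
                            introduction_cost = 0,
                            market_behavior = c("expand", "replace"),
                            eligible_population_filter = NULL,
                            specificity = 0.95,
                            device_lifetime_years = 1,
                            downstream_treatment_coverage = 1) {
  market_behavior <- match.arg(market_behavior)
  peak_coverage <- complete_setting_vector(peak_coverage, "peak_coverage")
  effectiveness <- complete_setting_vector(effectiveness, "effectiveness")

  spec <- structure(
    list(
      innovation_id = as.character(innovation_id),
      condition_id = as.character(condition_id),
      mechanism = as.character(mechanism),
      launch_year = as.integer(launch_year),
      ramp_years = as.integer(ramp_years),
      unit_cost = as.numeric(unit_cost),
      units_per_person_covered = as.numeric(units_per_person_covered),
      introduction_cost = as.numeric(introduction_cost),
      peak_coverage = peak_coverage,
      effectiveness = effectiveness,
      market_behavior = market_behavior,
      eligible_population_filter = eligible_population_filter,
      specificity = as.numeric(specificity),
      device_lifetime_years = as.numeric(device_lifetime_years),
      downstream_treatment_coverage = as.numeric(downstream_treatment_coverage)
    ),
    class = "innovation_spec"
  )
  validate_innovation_spec(spec)
  spec
}

# Coerce a (possibly partial) named per-setting vector to home/clinic/hospital.
complete_setting_vector <- function(x, what) {
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x))) {
    if (length(x) == 1L) {
      x <- setNames(rep(as.numeric(x), 3L), .settings)
    } else if (length(x) == 3L) {
      names(x) <- .settings
    } else {
      abort(sprintf("`%s` must be named by setting or have length 1 or 3.", what))
    }
  }
  bad <- setdiff(names(x), .settings)
  if (length(bad) > 0) {
    abort(sprintf("Unknown setting(s) in `%s`: %s.", what,
                  paste(bad, collapse = ", ")))
  }
  out <- setNames(rep(NA_real_, 3L), .settings)
  out[names(x)] <- as.numeric(x)
  out
}

validate_innovation_spec <- function(spec) {
  if (!spec$condition_id %in% condition_ids()) {
    abort(sprintf("Unknown condition_id '%s'. Known: %s.",
                  spec$condition_id, paste(condition_ids(), collapse = ", ")))
  }
  if (!spec$mechanism %in% mechanism_ids()) {
    abort(sprintf("Unknown mechanism '%s'. Known: %s.",
                  spec$mechanism, paste(mechanism_ids(), collapse = ", ")))
  }
  if (is.na(spec$ramp_years) || spec$ramp_years < 1L) {
    abort("`ramp_years` must be >= 1.")
  }
  if (is.na(spec$unit_cost) || spec$unit_cost < 0) {
    abort("`unit_cost` must be >= 0.")
  }
  if (spec$introduction_cost < 0) abort("`introduction_cost` must be >= 0.")
  if (spec$units_per_person_covered <= 0) {
    abort("`units_per_person_covered` must be > 0.")
  }
  if (spec$device_lifetime_years < 1) {
    abort("`device_lifetime_years` must be >= 1.")
  }
  for (fld in c("peak_coverage", "effectiveness")) {
    v <- spec[[fld]]
    bad <- !is.na(v) & (v < 0 | v > 1)
    if (any(bad)) {
      abort(sprintf("`%s` out of [0, 1] in setting(s): %s.",
                    fld, paste(names(v)[bad], collapse = ", ")))
    }
  }
  if (all(is.na(spec$peak_coverage))) {
    abort("At least one setting must carry a non-missing `peak_coverage`.")
  }
  active <- !is.na(spec$peak_coverage) & spec$peak_coverage > 0
  missing_eff <- active & is.na(spec$effectiveness)
  if (any(missing_eff)) {
    abort(sprintf(
      "Settings with peak coverage need an effectiveness value: %s.",
      paste(names(spec$peak_coverage)[missing_eff], collapse = ", ")
    ))
  }
  if (!is_fraction(spec$specificity)) abort("`specificity` must be in [0, 1].")
  if (!is_fraction(spec$downstream_treatment_coverage)) {
    abort("`downstream_treatment_coverage` must be in [0, 1].")
  }
  invisible(spec)
}

#' @export
print.innovation_spec <- function(x, ...) {
  cat(sprintf("<innovation_spec> %s\n", x$innovation_id))
  cat(sprintf("  condition:  %s\n", x$condition_id))
  cat(sprintf("  mechanism:  %s (%s)\n", x$mechanism, x$market_behavior))
  cat(sprintf("  launch:     %d (ramp %d y)\n", x$launch_year, x$ramp_years))
  cat(sprintf("  unit cost:  $%.2f (%g person(s)/unit)\n",
              x$unit_cost, x$units_per_person_covered))
  fmt <- function(v) paste(sprintf("%s=%s", names(v),
                                   ifelse(is.na(v), "NA", format(v))),
                           collapse = " ")
  cat(sprintf("  peak cov:   %s\n", fmt(x$peak_coverage)))
  cat(sprintf("  effect:     %s\n", fmt(x$effectiveness)))
  if (!is.null(x$eligible_population_filter)) {
    cat(sprintf("  eligibility: %s\n", x$eligible_population_filter))
  }
  invisible(x)
}

#' Null innovation (no-op scenario)
#'
#' Convenience spec with zero peak coverage everywhere; running it through
#' the scenario engine reproduces the baseline exactly, which is useful for
#' smoke tests and as the comparator sanity check.
#'
#' @param condition_id One of [condition_ids()].
#' @return An `innovation_spec` with zero coverage.
#' @export
null_innovation <- function(condition_id = "diarrhea") {
  innovation_spec(
    innovation_id = "null",
    condition_id = condition_id,
    mechanism = "incidence_reduction",
    launch_year = 2015L,
    unit_cost = 0,
    peak_coverage = c(home = 0, clinic = 0, hospital = 0),
    effectiveness = c(home = 0, clinic = 0, hospital = 0)
  )
}

#' Read / write an innovation specification
#'
#' Specs serialize to JSON or YAML (chosen by file extension) with the same
#' field names as [innovation_spec()]; per-setting fields are maps with
#' home/clinic/hospital keys and `null` for not-applicable settings.
#'
#' @param path File path ending in `.json`, `.yaml`, or `.yml`.
#' @return `read_innovation_spec()` returns an `innovation_spec`;
#'   `write_innovation_spec()` returns `path` invisibly.
#' @export
read_innovation_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    abort(sprintf("Unsupported innovation spec format '.%s' (use json/yaml).", ext))
  )
  spec_from_list(raw)
}

spec_from_list <- function(raw) {
  req <- c("innovation_id", "condition_id", "mechanism", "launch_year",
           "unit_cost", "peak_coverage", "effectiveness")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Innovation spec missing field(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  null_to_na <- function(v) {
    if (is.list(v)) v <- lapply(v, function(e) if (is.null(e)) NA_real_ else e)
    unlist(v)
  }
  innovation_spec(
    innovation_id = raw$innovation_id,
    condition_id = raw$condition_id,
    mechanism = raw$mechanism,
    launch_year = raw$launch_year,
    unit_cost = raw$unit_cost,
    peak_coverage = null_to_na(raw$peak_coverage),
    effectiveness = null_to_na(raw$effectiveness),
    ramp_years = raw$ramp_years %||% 5L,
    units_per_person_covered = raw$units_per_person_covered %||% 1,
    introduction_cost = raw$introduction_cost %||% 0,
    market_behavior = raw$market_behavior %||% "expand",
    eligible_population_filter = raw$eligible_population_filter,
    specificity = raw$specificity %||% 0.95,
    device_lifetime_years = raw$device_lifetime_years %||% 1,
    downstream_treatment_coverage = raw$downstream_treatment_coverage %||% 1
  )
}

#' @rdname read_innovation_spec
#' @param spec An `innovation_spec`.
#' @export
write_innovation_spec <- function(spec, path) {
  stopifnot(inherits(spec, "innovation_spec"))
  ext <- tolower(tools::file_ext(path))
  out <- unclass(spec)
  na_to_null <- function(v) lapply(as.list(v), function(e) if (is.na(e)) NULL else e)
  out$peak_coverage <- na_to_null(out$peak_coverage)
  out$effectiveness <- na_to_null(out$effectiveness)
  switch(ext,
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(out, path),
    abort(sprintf("Unsupported innovation spec format '.%s' (use json/yaml).", ext))
  )
  invisible(path)
}
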