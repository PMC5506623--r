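#' Adoption coverage in a given year
#'
#' Adoption ramps linearly from launch to per-setting peak coverage over
#' `ramp_years`: coverage is 0 before `launch_year`, the launch year itself
#' carries `1/ramp_years` of peak, and peak is reached in
#' `launch_year + ramp_years - 1`. With the default five-year ramp and a 2022
#' launch, a 25% peak gives 5% in 2022, 15% in 2024, and 25% from 2026 on.
#'
#' @param spec An [innovation_spec()].
#' @param year Calendar year (vectorized).
#' @param setting One of `"home"`, `"clinic"`, `"hospital"`, or `NULL` to
#'   get a setting-by-year matrix.
#' @return Numeric vector of coverage fractions (missing peaks count as 0),
#'   or a matrix with one row per setting when `setting` is `NULL`.
#' @export
#' @examples
#' oxy <- builtin_preset("oxytocin_new_formulation")
#' coverage_at_year(oxy, 2021:2027, setting = "home")
coverage_at_year <- function(spec, year, setting = NULL) {
  frac <- ramp_fraction(spec, year)
  peak <- spec$peak_coverage
  peak[is.na(peak)] <- 0
  if (is.null(setting)) {
    out <- outer(peak, frac)
    dimnames(out) <- list(.settings, as.character(year))
    return(out)
  }
  if (!setting %in% .settings) {
    abort(sprintf("Unknown setting '%s'.", setting))
  }
  unname(peak[setting] * frac)
}

# Fraction of peak reached in each year: 0 pre-launch, linear to 1.
ramp_fraction <- function(spec, year) {
  pmax(0, pmin(1, (year - spec$launch_year + 1) / spec$ramp_years))
}

#' Mechanism primitive: incidence reduction
#'
#' A preventive innovation (e.g. community water chlorination) lowers
#' condition incidence among the covered, eligible share of the population:
#' `incidence * (1 - eligible_fraction * coverage * effectiveness)`.
#'
#' @param incidence Events per person at risk per year (may exceed 1 for
#'   diarrhea episodes).
#' @param coverage Ramped adoption fraction.
#' @param effectiveness Fractional incidence reduction among covered users.
#' @param eligible_fraction Share of the population the innovation can reach
#'   (e.g. community-water users). Default 1.
#' @return Adjusted incidence.
#' @export
#' @examples
#' apply_incidence_reduction(3.3, coverage = 0.25, effectiveness = 0.84)
apply_incidence_reduction <- function(incidence, coverage, effectiveness,
                                      eligible_fraction = 1) {
  check_fractions(coverage = coverage, effectiveness = effectiveness,
                  eligible_fraction = eligible_fraction)
  incidence * (1 - eligible_fraction * coverage * effectiveness)
}

#' Mechanism primitive: case-fatality reduction
#'
#' A mortality-reducing innovation (e.g. chlorhexidine cord care) multiplies
#' the case fatality rate in its gated settings by
#' `1 - coverage * mortality_reduction`.
#'
#' @param cfr Case fatality rate (deaths per case).
#' @param coverage Ramped adoption fraction among the gated population.
#' @param mortality_reduction Fractional CFR reduction at full coverage.
#' @return Adjusted CFR.
#' @export
#' @examples
#' apply_mortality_reduction(0.12, coverage = 0.55, mortality_reduction = 0.23)
apply_mortality_reduction <- function(cfr, coverage, mortality_reduction) {
  check_fractions(cfr = cfr, coverage = coverage,
                  mortality_reduction = mortality_reduction)
  cfr * (1 - coverage * mortality_reduction)
}

#' Mechanism primitive: treatment coverage expansion
#'
#' An innovation that brings treatment to unreached cases either expands the
#' market (`baseline + innovation`, capped at 1 with a clipping warning) or
#' replaces existing market share (`max(baseline, innovation)`).
#'
#' @param baseline_coverage Comparator treatment coverage.
#' @param innovation_coverage Ramped innovation coverage.
#' @param market_behavior `"expand"` or `"replace"`.
#' @return Total treatment coverage after introduction.
#' @export
#' @examples
#' apply_coverage_expansion(0.3, 0.25, "expand")
apply_coverage_expansion <- function(baseline_coverage, innovation_coverage,
                                     market_behavior = c("expand", "replace")) {
  market_behavior <- match.arg(market_behavior)
  check_fractions(baseline_coverage = baseline_coverage,
                  innovation_coverage = innovation_coverage)
  if (market_behavior == "expand") {
    total <- baseline_coverage + innovation_coverage
    if (any(total > 1 + 1e-12)) {
      warn("Expanded treatment coverage exceeds 1; clipping to 1.")
    }
    pmin(1, total)
  } else {
    pmax(baseline_coverage, innovation_coverage)
  }
}

# Market-share decomposition behind apply_coverage_expansion: how much of
# post-introduction coverage is served by the comparator vs the innovation.
expansion_shares <- function(baseline_coverage, innovation_coverage,
                             market_behavior) {
  if (market_behavior == "expand") {
    total <- pmin(1, baseline_coverage + innovation_coverage)
    innovation <- total - baseline_coverage
    comparator <- baseline_coverage
  } else {
    total <- pmax(baseline_coverage, innovation_coverage)
    innovation <- pmin(innovation_coverage, total)
    comparator <- total - innovation
  }
  list(total = total, comparator = comparator, innovation = innovation)
}

#' Mechanism primitive: second-line treatment
#'
#' A rescue intervention (e.g. uterine balloon tamponade after uterotonic
#' failure) treats `failures * coverage * effectiveness` additional cases;
#' these move from the untreated to the treated case fatality rate.
#'
#' @param uterotonic_failures Count of first-line treatment failures in the
#'   setting (any first-line failure pool; named for the motivating use).
#' @param coverage Ramped innovation coverage among failures.
#' @param effectiveness Fraction of covered failures in which the rescue
#'   works.
#' @return Count of additionally effectively-treated cases.
#' @export
#' @examples
#' apply_second_line(1000, coverage = 0.75, effectiveness = 0.85)
apply_second_line <- function(uterotonic_failures, coverage, effectiveness) {
  check_fractions(coverage = coverage, effectiveness = effectiveness)
  stopifnot(all(uterotonic_failures >= 0))
  uterotonic_failures * coverage * effectiveness
}

#' Mechanism primitive: adherence / coverage boost
#'
#' An adjunct product (e.g. new diarrhea treatments taken with ORS) raises
#' coverage of an existing intervention by a fixed number of percentage
#' points, scaled by the adoption ramp and capped at 1 (with a clipping
#' warning). The boosted intervention keeps its own effectiveness.
#'
#' @param baseline_ors_coverage Baseline coverage of the boosted intervention
#'   (named for the motivating ORS use; any intervention works).
#' @param boost_points Percentage-point boost at peak, as a fraction
#'   (0.15 = 15 points).
#' @param ramp_fraction Fraction of peak adoption reached this year
#'   (`coverage_at_year / peak`), default 1.
#' @return Boosted coverage.
#' @export
#' @examples
#' apply_adherence_boost(0.40, boost_points = 0.15)
apply_adherence_boost <- function(baseline_ors_coverage, boost_points,
                                  ramp_fraction = 1) {
  check_fractions(baseline_ors_coverage = baseline_ors_coverage,
                  boost_points = boost_points, ramp_fraction = ramp_fraction)
  boosted <- baseline_ors_coverage + boost_points * ramp_fraction
  if (any(boosted > 1 + 1e-12)) {
    warn("Boosted coverage exceeds 1; clipping to 1.")
  }
  pmin(1, boosted)
}

#' Mechanism primitive: diagnostic improvement
#'
#' A diagnostic device screens the covered share of presenting patients.
#' True cases are diagnosed with probability `detection_prob` and a
#' `downstream_treatment_coverage` fraction of them receive treatment.
#' Non-cases are falsely diagnosed with probability `1 - specificity`;
#' false positives incur treatment costs but no mortality benefit.
#'
#' @param presenting_cases True condition cases presenting in the setting.
#' @param presenting_noncases Symptomatic non-cases presenting alongside.
#' @param coverage Ramped device coverage of presenting patients.
#' @param detection_prob Device sensitivity (probability a true case is
#'   detected).
#' @param specificity Probability a non-case is correctly ruled out.
#' @param downstream_treatment_coverage Fraction of positive diagnoses that
#'   go on to treatment. Default 1.
#' @return List with `diagnosed_treated` (true cases diagnosed by the device
#'   and treated) and `false_positive_treatments`.
#' @export
#' @examples
#' apply_diagnostic(1000, 3000, coverage = 0.8, detection_prob = 0.85,
#'                  specificity = 0.95)
apply_diagnostic <- function(presenting_cases, presenting_noncases, coverage,
                             detection_prob, specificity,
                             downstream_treatment_coverage = 1) {
  check_fractions(coverage = coverage, detection_prob = detection_prob,
                  specificity = specificity,
                  downstream_treatment_coverage = downstream_treatment_coverage)
  stopifnot(all(presenting_cases >= 0), all(presenting_noncases >= 0))
  list(
    diagnosed_treated = presenting_cases * coverage * detection_prob *
      downstream_treatment_coverage,
    false_positive_treatments = presenting_noncases * coverage *
      (1 - specificity) * downstream_treatment_coverage
  )
}

check_fractions <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(is.na(v) | v < -1e-12 | v > 1 + 1e-12)) {
      abort(sprintf("`%s` must be in [0, 1].", nm))
    }
  }
  invisible(TRUE)
}
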