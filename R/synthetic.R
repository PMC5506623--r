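#' Configuration for the synthetic country-table generator
#'
#' The generator emulates the statistical shape of the model's real inputs —
#' country-level population denominators, condition incidence, the
#' home/clinic/hospital presentation mix, baseline standard-of-care coverage
#' and effectiveness, treated/untreated case fatality rates, and per-case
#' treatment costs — without attempting to match any real country's
#' demography. Diarrhea incidence defaults to the 2.4–3.3 episodes per
#' child-year range reported for South-East Asia and sub-Saharan Africa;
#' the remaining ranges are package choices of plausible magnitudes for
#' high-burden settings. Country parameters are drawn once per country and
#' held constant over the horizon except for births, which drift by a small
#' annual growth rate.
#'
#' @param seed Integer seed; identical seed and config give an identical
#'   table.
#' @param n_countries Number of synthetic countries.
#' @param conditions Conditions to generate; default all of
#'   [condition_ids()].
#' @param horizon Length-2 year range, default `c(2015, 2030)`.
#' @param live_births_range Annual live births per country.
#' @param incidence_ranges Named list of per-condition incidence ranges
#'   (events per person at risk per year).
#' @param setting_mix_concentration Dirichlet concentration for the
#'   home/clinic/hospital presentation mix (home-heavy by default, as in
#'   high-burden settings).
#' @param coverage_ranges Named list of per-setting baseline coverage
#'   ranges.
#' @param effectiveness_range Baseline intervention effectiveness range.
#' @param cfr_untreated_ranges Named list of per-condition untreated CFR
#'   ranges.
#' @param cfr_treated_ratio_range Treated CFR as a fraction of untreated
#'   (drawn below 1 so `cfr_treated < cfr_untreated` always holds).
#' @param cost_ranges Named list of per-setting treatment cost (USD) ranges.
#' @param eligible_fraction_range Range of the population share an
#'   eligibility-gated innovation can reach (e.g. community-water users).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed,
                         n_countries = 5L,
                         conditions = condition_ids(),
                         horizon = c(2015L, 2030L),
                         live_births_range = c(5e4, 5e5),
                         incidence_ranges = list(
                           diarrhea = c(2.4, 3.3),
                           pneumonia = c(0.2, 0.4),
                           neonatal_sepsis = c(0.02, 0.06),
                           pph = c(0.03, 0.08),
                           obstructed_labor = c(0.02, 0.06)
                         ),
                         setting_mix_concentration = c(home = 5, clinic = 3,
                                                       hospital = 2),
                         coverage_ranges = list(home = c(0.1, 0.4),
                                                clinic = c(0.3, 0.7),
                                                hospital = c(0.5, 0.9)),
                         effectiveness_range = c(0.5, 0.9),
                         cfr_untreated_ranges = list(
                           diarrhea = c(5e-4, 2e-3),
                           pneumonia = c(0.01, 0.05),
                           neonatal_sepsis = c(0.10, 0.30),
                           pph = c(0.01, 0.05),
                           obstructed_labor = c(0.02, 0.08)
                         ),
                         cfr_treated_ratio_range = c(0.1, 0.5),
                         cost_ranges = list(home = c(1, 5),
                                            clinic = c(5, 20),
                                            hospital = c(20, 100)),
                         eligible_fraction_range = c(0.4, 0.9)) {
  cfg <- structure(
    list(seed = as.integer(seed), n_countries = as.integer(n_countries),
         conditions = conditions, horizon = as.integer(horizon),
         live_births_range = live_births_range,
         incidence_ranges = incidence_ranges,
         setting_mix_concentration = setting_mix_concentration,
         coverage_ranges = coverage_ranges,
         effectiveness_range = effectiveness_range,
         cfr_untreated_ranges = cfr_untreated_ranges,
         cfr_treated_ratio_range = cfr_treated_ratio_range,
         cost_ranges = cost_ranges,
         eligible_fraction_range = eligible_fraction_range),
    class = "synth_config"
  )
  bad_cond <- setdiff(cfg$conditions, condition_ids())
  if (length(bad_cond) > 0) {
    abort(sprintf("Unknown condition(s): %s.", paste(bad_cond, collapse = ", ")))
  }
  ranges <- c(list(cfg$live_births_range, cfg$effectiveness_range,
                   cfg$cfr_treated_ratio_range, cfg$eligible_fraction_range),
              cfg$incidence_ranges[cfg$conditions],
              cfg$coverage_ranges, cfg$cost_ranges,
              cfg$cfr_untreated_ranges[cfg$conditions])
  for (r in ranges) {
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2]) {
      abort("Every range must be c(min, max) with min <= max.")
    }
  }
  missing <- setdiff(cfg$conditions, names(cfg$incidence_ranges))
  if (length(missing) > 0) {
    abort(sprintf("No incidence range for: %s.", paste(missing, collapse = ", ")))
  }
  cfg
}

#' Generate a seeded synthetic country-year table
#'
#' @param config A [synth_config()].
#' @return A `country_table` covering every (country, year, condition) cell
#'   of the config, deterministic in the seed and guaranteed to pass
#'   [validate_inputs()].
#' @export
#' @examples
#' tbl <- generate_country_inputs(synth_config(seed = 42, n_countries = 2))
#' nrow(tbl)  # 2 countries x 16 years x 5 conditions
generate_country_inputs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  years <- seq(config$horizon[1], config$horizon[2])
  n <- config$n_countries
  codes <- vapply(seq_len(n), function(i) {
    paste0("S", LETTERS[(i - 1) %/% 26 + 1], LETTERS[(i - 1) %% 26 + 1])
  }, character(1))
  ru <- function(range, k = 1) runif(k, range[1], range[2])

  withr::with_seed(config$seed, {
    rows <- purrr::map_dfr(seq_len(n), function(i) {
      births0 <- ru(config$live_births_range)
      growth <- runif(1, -0.005, 0.02)
      preg_ratio <- runif(1, 1.05, 1.15)
      under5_ratio <- runif(1, 4.2, 4.8)
      g <- stats::rgamma(3, shape = config$setting_mix_concentration)
      mix <- g / sum(g)
      eligible <- ru(config$eligible_fraction_range)

      purrr::map_dfr(config$conditions, function(cond) {
        incidence <- ru(config$incidence_ranges[[cond]])
        cov <- vapply(.settings, function(s) ru(config$coverage_ranges[[s]]),
                      numeric(1))
        eff <- setNames(ru(config$effectiveness_range, 3), .settings)
        cfr_u <- setNames(ru(config$cfr_untreated_ranges[[cond]], 3), .settings)
        cfr_t <- cfr_u * ru(config$cfr_treated_ratio_range, 3)
        cost <- vapply(.settings, function(s) ru(config$cost_ranges[[s]]),
                       numeric(1))
        births <- births0 * (1 + growth)^(years - years[1])
        tibble::tibble(
          country_code = codes[i],
          year = years,
          condition_id = cond,
          live_births = births,
          neonates = births,
          pregnancies = births * preg_ratio,
          under5_population = births * under5_ratio,
          incidence = incidence,
          setting_mix_home = mix[1],
          setting_mix_clinic = mix[2],
          setting_mix_hospital = mix[3],
          baseline_coverage_home = cov[["home"]],
          baseline_coverage_clinic = cov[["clinic"]],
          baseline_coverage_hospital = cov[["hospital"]],
          baseline_effectiveness_home = eff[["home"]],
          baseline_effectiveness_clinic = eff[["clinic"]],
          baseline_effectiveness_hospital = eff[["hospital"]],
          cfr_treated_home = cfr_t[["home"]],
          cfr_treated_clinic = cfr_t[["clinic"]],
          cfr_treated_hospital = cfr_t[["hospital"]],
          cfr_untreated_home = cfr_u[["home"]],
          cfr_untreated_clinic = cfr_u[["clinic"]],
          cfr_untreated_hospital = cfr_u[["hospital"]],
          treatment_cost_per_case_home = cost[["home"]],
          treatment_cost_per_case_clinic = cost[["clinic"]],
          treatment_cost_per_case_hospital = cost[["hospital"]],
          eligible_fraction = eligible
        )
      })
    })
    as_country_table(rows)
  })
}

#' Per-individual microsimulation oracle
#'
#' A brute-force stochastic realization of the cascade used to validate the
#' deterministic engine: each simulated case candidate independently draws
#' its presentation setting, whether prevention stops the case, whether it
#' is covered by first-line care, whether treatment works, any innovation
#' mechanism event, and finally death by the applicable case fatality rate.
#' The mean death indicator, scaled to the expected case count, estimates
#' the country-year's deaths with a binomial-style standard error. Cases
#' (episodes, for diarrhea) are simulated rather than the whole population
#' at risk, so rare conditions need no oversampling.
#'
#' @param inputs A single country-table row.
#' @param innovation Optional [innovation_spec()] (same condition); `NULL`
#'   simulates the baseline standard of care.
#' @param n_individuals Number of simulated case candidates (>= 1000).
#' @param seed Integer seed for the one pseudo-random stream of the call.
#' @param config A [model_config()].
#' @return A `microsim_estimate`: list with `estimate` (expected deaths),
#'   `se`, `n_individuals`, and `seed`.
#' @export
microsim_oracle <- function(inputs, innovation = NULL, n_individuals = 2e5,
                            seed = 1L, config = model_config()) {
  df <- tibble::as_tibble(inputs)
  if (nrow(df) != 1L) abort("`inputs` must be a single country-table row.")
  if (n_individuals < 1000) abort("`n_individuals` must be >= 1000.")
  n <- as.integer(n_individuals)
  if (!is.null(innovation)) {
    stopifnot(inherits(innovation, "innovation_spec"))
    if (innovation$condition_id != df$condition_id) {
      abort("Innovation condition does not match the input row.")
    }
  }

  expected_cases <- cases_for_year(df)
  mix <- c(df$setting_mix_home, df$setting_mix_clinic, df$setting_mix_hospital)
  base_cov <- vapply(.settings, function(s) df[[paste0("baseline_coverage_", s)]],
                     numeric(1))
  base_eff <- vapply(.settings,
                     function(s) df[[paste0("baseline_effectiveness_", s)]],
                     numeric(1))
  cfr_t <- vapply(.settings, function(s) df[[paste0("cfr_treated_", s)]],
                  numeric(1))
  cfr_u <- vapply(.settings, function(s) df[[paste0("cfr_untreated_", s)]],
                  numeric(1))

  mech <- if (is.null(innovation)) "baseline" else innovation$mechanism
  if (mech == "baseline") {
    cov_s <- setNames(rep(0, 3), .settings)
    eff_s <- cov_s
    elig <- 1
  } else {
    peak <- innovation$peak_coverage
    effv <- innovation$effectiveness
    rampf <- ramp_fraction(innovation, df$year)
    cov_s <- ifelse(is.na(peak), 0, peak) * rampf
    eff_s <- ifelse(is.na(effv), 0, effv)
    gate <- innovation$eligible_population_filter
    elig <- if (!is.null(gate) &&
                gate %in% c("community_water", "eligible_fraction")) {
      df$eligible_fraction
    } else {
      1
    }
  }

  death <- withr::with_seed(seed, {
    s <- sample.int(3L, n, replace = TRUE, prob = mix)
    prevented <- rep(FALSE, n)
    te <- logical(n)
    cfr_t_i <- cfr_t[s]
    cfr_u_i <- cfr_u[s]

    if (mech == "incidence_reduction") {
      active <- which(!is.na(innovation$peak_coverage))
      lead <- active[which.max(innovation$peak_coverage[active])]
      p_prev <- elig * cov_s[lead] * eff_s[lead]
      # skip the draw at p = 0 so a null innovation shares the baseline stream
      if (p_prev > 0) prevented <- runif(n) < p_prev
      te <- runif(n) < base_cov[s] & runif(n) < base_eff[s]
    } else if (mech == "mortality_reduction") {
      te <- runif(n) < base_cov[s] & runif(n) < base_eff[s]
      covered <- runif(n) < elig * cov_s[s]
      mult <- ifelse(covered, 1 - eff_s[s], 1)
      cfr_t_i <- cfr_t_i * mult
      cfr_u_i <- cfr_u_i * mult
    } else if (mech == "coverage_expansion") {
      sh <- expansion_shares(base_cov, elig * cov_s,
                             innovation$market_behavior)
      u <- runif(n)
      comp <- u < sh$comparator[s]
      innov <- !comp & u < (sh$comparator[s] + sh$innovation[s])
      te <- (comp & runif(n) < base_eff[s]) | (innov & runif(n) < eff_s[s])
    } else if (mech == "second_line_treatment") {
      covered <- runif(n) < base_cov[s]
      works <- runif(n) < base_eff[s]
      te <- covered & works
      pool <- (covered & !works)
      if (config$second_line_pool == "all_failures") pool <- pool | !covered
      rescued <- pool & runif(n) < elig * cov_s[s] & runif(n) < eff_s[s]
      te <- te | rescued
    } else if (mech == "adherence_boost") {
      boosted <- pmin(1, base_cov + eff_s * ramp_fraction(innovation, df$year) *
                        elig * as.numeric(!is.na(innovation$peak_coverage)))
      te <- runif(n) < boosted[s] & runif(n) < base_eff[s]
    } else if (mech == "diagnostic_improvement") {
      add_cov <- elig * cov_s * pmax(0, eff_s - base_cov) *
        innovation$downstream_treatment_coverage
      treat_cov <- pmin(1, base_cov + add_cov)
      te <- runif(n) < treat_cov[s] & runif(n) < base_eff[s]
    } else {
      te <- runif(n) < base_cov[s] & runif(n) < base_eff[s]
    }

    !prevented & runif(n) < ifelse(te, cfr_t_i, cfr_u_i)
  })

  structure(
    list(
      estimate = mean(death) * expected_cases,
      se = stats::sd(death) / sqrt(n) * expected_cases,
      n_individuals = n,
      seed = as.integer(seed)
    ),
    class = "microsim_estimate"
  )
}

#' @export
print.microsim_estimate <- function(x, ...) {
  cat(sprintf("<microsim_estimate> %.2f deaths (SE %.3f, n = %d, seed %d)\n",
              x$estimate, x$se, x$n_individuals, x$seed))
  invisible(x)
}
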