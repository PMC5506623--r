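#' Model configuration
#'
#' Bundles the run-level knobs of the forecast engine.
#'
#' @param horizon Length-2 integer vector, first and last modeled year
#'   (inclusive). Default `c(2015, 2030)`.
#' @param second_line_pool Which first-line failures a second-line treatment
#'   can rescue: `"treated_failures"` (covered-but-ineffective first-line
#'   cases, the default) or `"all_failures"` (also first-line-untreated
#'   cases).
#' @param noncase_multiple Symptomatic non-cases presenting per true case,
#'   used by the diagnostic false-positive cost pathway. Default 3.
#' @param discount_rate Annual discount rate applied to costs and deaths;
#'   default 0 (no discounting).
#' @return A list with class `impact_config`.
#' @export
model_config <- function(horizon = c(2015L, 2030L),
                         second_line_pool = c("treated_failures", "all_failures"),
                         noncase_multiple = 3,
                         discount_rate = 0) {
  second_line_pool <- match.arg(second_line_pool)
  horizon <- as.integer(horizon)
  if (length(horizon) != 2L || any(is.na(horizon)) || horizon[1] > horizon[2]) {
    abort("`horizon` must be two years, first <= last.")
  }
  if (noncase_multiple < 0) abort("`noncase_multiple` must be >= 0.")
  if (discount_rate < 0 || discount_rate >= 1) {
    abort("`discount_rate` must be in [0, 1).")
  }
  structure(
    list(horizon = horizon, second_line_pool = second_line_pool,
         noncase_multiple = noncase_multiple, discount_rate = discount_rate),
    class = "impact_config"
  )
}
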