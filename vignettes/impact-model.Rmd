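---
title: "The mnchimpact forecast model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mnchimpact forecast model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnchimpact)
```

## The model

`mnchimpact` forecasts, country by country and year by year, how many
deaths from a maternal, newborn, or child health condition would occur
under the current standard of care, and how many would occur if one new
innovation were introduced. The difference, summed over a roster of
countries and a 2015–2030 horizon, is the innovation's incremental lives
saved; a parallel costing layer gives its incremental cost.

The deterministic core is a cascade of expectations. For a country-year of
one condition:

1. **Cases.** The population at risk (pregnancies for postpartum
   hemorrhage and obstructed labor, neonates for sepsis, children under
   five for diarrhea and pneumonia) is multiplied by incidence. Diarrhea
   incidence is episodes per child-year and may exceed one; "cases" are
   then episodes.
2. **Setting split.** Cases present in home, clinic, or hospital settings
   according to a presentation mix that sums to one.
3. **Treatment.** Within each setting, a fraction
   `coverage × effectiveness` of cases is *effectively* treated. Coverage
   is availability-and-use; effectiveness is real-world efficacy. We treat
   the two as independent multiplicative fractions; whether "successful
   receipt" should instead be a single measured quantity is not decidable
   from the available evidence, so the multiplicative contract is simply
   documented here as this package's contract.
4. **Deaths.** A case fatality rate (CFR) is applied separately to
   effectively treated and to untreated cases and summed.

Deaths are real-valued expectations throughout; nothing is rounded until
report time. Two runs with identical inputs are bitwise identical: the
deterministic engine consumes no randomness.

Baseline inputs (coverage, effectiveness, CFRs, mix) are held constant
over the horizon unless the input table varies them by year. Historical
trends in care-seeking may well continue, but extrapolating them requires
a trend model the inputs do not constrain, so none is imposed. No
discounting is applied by default; `model_config(discount_rate = )` exists
for users who want it.

## Innovation mechanisms

An innovation is a data object (`innovation_spec()`), not code: mechanism
selection and every parameter are read from the spec, so nothing about a
mechanism is tied to an innovation's name. Adoption follows a linear ramp:
zero before the launch year, `1/ramp_years` of peak in the launch year
itself, peak from `launch_year + ramp_years − 1` on. The no-dead-launch
convention (the launch year already carries a first increment) is a
package choice; a five-year "time to peak" alone does not fix where the
first step lands, and starting at zero would make the nominal launch year
a year of no adoption.

The six mechanism classes, and their exact semantics:

* **Incidence reduction** (e.g. community water chlorination). Incidence
  is multiplied by `1 − eligible × coverage × effectiveness` *before* the
  setting split: prevention acts on the whole eligible population, so
  cases fall in every presentation setting, not only the setting that
  carries the adoption parameter.
* **Mortality reduction** (e.g. chlorhexidine cord care). Both CFRs in the
  gated settings are multiplied by `1 − coverage × reduction`. The
  reduction is applied to the condition-specific CFR (sepsis deaths among
  covered home births), not to all-cause neonatal mortality, because the
  model is condition-specific.
* **Coverage expansion** (e.g. heat-stable oxytocin, Odon device). With
  `expand` semantics the innovation adds market share on top of the
  comparator, capped at one (with a clipping warning); with `replace` it
  takes over comparator share. The expanded share is treated with the
  innovation's own effectiveness — equal to the comparator's for oxytocin,
  by assumption of equivalence.
* **Second-line treatment** (uterine balloon tamponade). The eligible pool
  defaults to first-line *treated* failures (covered but ineffective);
  `model_config(second_line_pool = "all_failures")` widens it to untreated
  cases too. "All women who fail uterotonic drugs" is ambiguous between
  the two readings; the narrower pool is the default because an untreated
  woman has, strictly, not failed a drug she never received.
* **Adherence boost** (new diarrhea treatments). The product is not
  independently effective; it raises ORS coverage by a fixed
  percentage-point boost (0.15 at peak), scaled by the adoption ramp and
  capped at one. ORS keeps its own baseline effectiveness.
* **Diagnostic improvement** (pulse oximeter, respiratory rate monitor).
  For the covered share of presenting cases the diagnosis probability
  becomes `max(baseline coverage, device detection)` — replace-if-better —
  so a device no better than the standard pathway averts exactly zero
  deaths, and a diagnostic can never increase them. Non-cases presenting
  alongside (3 per true case by default, a plausible symptomatic
  attendance ratio for pneumonia-like illness; `model_config(noncase_multiple = )`)
  are falsely diagnosed with probability `1 − specificity` and incur
  treatment costs with no mortality effect. Published parameters give no
  specificity for either device; 0.95 is a package default, configurable
  per spec, and worth including in any sensitivity analysis. Whether the
  published 85%/80% "effectiveness" is sensitivity alone or folds in
  referral is likewise unstated; it is read here as detection probability,
  with a separate `downstream_treatment_coverage` knob (default 1).

Every mechanism output is clamped to its domain; any clipping emits an R
warning rather than failing silently or raising an error.

### Eligibility gating

`eligible_fraction` lives on the country table because it is a property of
the country's population (e.g. the share using community water sources),
not of the innovation. The innovation's `eligible_population_filter` names
which gate applies: `community_water` multiplies reach by the column;
`home_births` is structural and is already encoded by restricting peak
coverage to the home setting, so the column is deliberately *not* applied
a second time.

## Costing

Incremental cost per year decomposes into four terms, each recomputable
from the scenario's cascade rows:

1. **Innovation spend** — units purchased times unit cost. Units are the
   ceiling of covered persons (or expected uses: doses, rescue attempts,
   screens) divided by `units_per_person_covered` (1000 people per batch
   chlorinator; 1000 screens per diagnostic device-year, a package
   estimate). By default units are purchased afresh each year
   (`device_lifetime_years = 1`); a longer lifetime amortizes the
   purchase.
2. **Introduction cost** — a one-time per-country charge booked in the
   launch year (timing is a package choice; only the existence of
   introduction costs is given).
3. **Downstream treatment costs** — additionally treated cases, true *and*
   false positive, times the setting's per-case treatment cost.
4. **Averted treatment costs** — prevented cases times the same per-case
   cost, subtracted.

Research-and-development and economic-productivity costs are out of scope.
Negative totals are reported as cost savings. Price never influences
coverage.

Results for two innovations against the same condition must not be added:
each scenario inserts exactly one innovation against the same baseline,
and the engine enforces one spec per run.

## Sensitivity analysis

`one_at_a_time_sensitivity()` varies one input at a time, all others at
central values, one full model re-run per perturbation: peak coverage and
effectiveness by ±5 percentage points (default) in every setting the
innovation enters, clipped to [0, 1] with a warning; unit cost over
user-supplied lower/upper bounds only, since no canonical cost ranges
exist to ship. Cost perturbations change costs and never deaths.

## The synthetic generator and the microsimulation oracle

No real country inputs ship with the package: assembling them requires
demographic, survey, and incidence sources that are deliberately out of
scope. `generate_country_inputs()` instead emulates the *structure* the
model assumes: per-country population denominators (50k–500k annual
births, with pregnancies, neonates, and under-five population derived by
plausible ratios), a home-heavy Dirichlet presentation mix, per-setting
baseline coverage rising from home to hospital, effectiveness in
0.5–0.9, condition-specific CFR magnitudes with treated CFR drawn strictly
below untreated, treatment costs rising by level of care, and diarrhea
incidence in the published 2.4–3.3 episodes/child-year band. Draws are
deterministic in the seed and every generated table passes
`validate_inputs()` by construction.

What the generator does **not** emulate: real country demographics or
their correlations, secular trends, within-country heterogeneity, seasonal
patterns, or data quality problems. Passing tests on synthetic tables
therefore validate the *engine* — its algebra, invariants, and
composition — not the realism of any forecast; headline magnitudes from
synthetic rosters are not comparable to published country-level estimates.

`microsim_oracle()` is the package's independent check on the engine: it
pushes `n` simulated case candidates through the cascade with independent
Bernoulli draws at every node (setting, prevention, coverage, treatment
success, mechanism event, death) and scales the mean death indicator to
the expected case count, with a binomial-style standard error. It
simulates cases rather than persons at risk, so rare conditions need no
oversampling, and draws episodes for diarrhea. Each call uses one
explicitly seeded stream; zero-probability mechanism events consume no
randomness, so a null innovation reproduces the baseline stream exactly.
The acceptance suite requires the deterministic engine to sit within four
standard errors of the oracle at n = 200,000 for all six mechanism
classes on three seeded fixtures each — a test that would catch any
mismatch between the engine's closed-form expectations and the process
they claim to summarize.

## Numerical choices and problem sizes

* Conservation (`treated + untreated = cases`) and the setting-mix sum are
  checked to 1e-9; hand-worked examples reproduce to 1e-9 or better.
* Fractions are validated to [0, 1] with a 1e-12 slack for floating-point
  drift; mechanism clipping warns and clamps.
* CSV serialization writes doubles at 17 significant digits and JSON at
  full precision, so write → load round-trips are bitwise lossless.
* Degenerate inputs: zero cases give zero deaths without division errors;
  zero-coverage innovations and post-horizon launches reproduce the
  baseline bitwise.
* Test problem sizes are chosen so the whole suite validates every
  property at comfortable scale: rosters of one to five synthetic
  countries over the full 16-year horizon, 5×5 parameter grids per
  mechanism for monotonicity, and 200,000-individual oracle runs.

## Known limitations

* One innovation per scenario; no interaction or joint scale-up modeling.
* No morbidity, stillbirth, or DALY outputs; deaths only, matching the
  mortality-target framing.
* No uncertainty propagation beyond one-at-a-time perturbation; no
  probabilistic calibration of inputs.
* The market model is limited to expand/replace shares; no price
  elasticity or competitive dynamics.
* Baseline care is static over the horizon; improvements in the standard
  of care would erode an innovation's incremental impact relative to
  these forecasts.
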