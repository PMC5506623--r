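test_that("adoption ramps linearly from launch to peak", {
  oxy <- builtin_preset("oxytocin_new_formulation")
  expect_identical(coverage_at_year(oxy, 2021, "home"), 0)
  expect_equal(coverage_at_year(oxy, 2024, "home"), 0.25 * 3 / 5,
               tolerance = 1e-12)
  expect_equal(coverage_at_year(oxy, 2026, "home"), 0.25)
  expect_equal(coverage_at_year(oxy, 2030, "home"), 0.25)
  # launch year carries 1/ramp_years of peak
  expect_equal(coverage_at_year(oxy, 2022, "home"), 0.25 / 5)
})

test_that("the ramp is piecewise-linear, non-decreasing, and continuous", {
  for (nm in preset_names()) {
    spec <- builtin_preset(nm)
    for (s in setting_ids()) {
      cov <- coverage_at_year(spec, 2015:2030, s)
      expect_true(all(diff(cov) >= -1e-12), label = paste(nm, s))
      # slope is 0 or peak/ramp_years everywhere (piecewise linear)
      slopes <- round(diff(cov), 12)
      peak <- spec$peak_coverage[s]
      if (!is.na(peak)) {
        expect_true(all(slopes %in% round(c(0, peak / spec$ramp_years), 12)),
                    label = paste(nm, s))
      }
    }
  }
})

test_that("incidence reduction scales with coverage, effectiveness, eligibility", {
  expect_equal(apply_incidence_reduction(3.3, 0.25, 0.84), 2.607,
               tolerance = 1e-12)
  expect_identical(apply_incidence_reduction(3.3, 0, 0.84), 3.3)
  full <- 3.3 - apply_incidence_reduction(3.3, 0.25, 0.84, eligible_fraction = 1)
  half <- 3.3 - apply_incidence_reduction(3.3, 0.25, 0.84, eligible_fraction = 0.5)
  expect_equal(half, full / 2, tolerance = 1e-12)
})

test_that("mortality reduction multiplies the CFR by 1 - coverage x reduction", {
  expect_equal(apply_mortality_reduction(1, 0.55, 0.23), 0.8735,
               tolerance = 1e-12)
  expect_equal(apply_mortality_reduction(1, 1, 0.23), 0.77, tolerance = 1e-12)
  expect_identical(apply_mortality_reduction(0.12, 0.55, 0), 0.12)
})

test_that("coverage expansion adds or replaces market share with a cap", {
  expect_equal(apply_coverage_expansion(0.3, 0.25, "expand"), 0.55,
               tolerance = 1e-12)
  expect_warning(out <- apply_coverage_expansion(0.9, 0.25, "expand"),
                 "[Cc]lip")
  expect_identical(out, 1)
  expect_identical(apply_coverage_expansion(0.3, 0, "replace"), 0.3)
  expect_equal(apply_coverage_expansion(0.3, 0.6, "replace"), 0.6)
})

test_that("second-line treatment rescues failures x coverage x effectiveness", {
  expect_equal(apply_second_line(1000, 0.75, 0.85), 637.5, tolerance = 1e-12)
  expect_identical(apply_second_line(1000, 0, 0.85), 0)
})

test_that("adherence boost adds ramped percentage points, capped at 1", {
  expect_equal(apply_adherence_boost(0.40, 0.15), 0.55, tolerance = 1e-12)
  expect_warning(out <- apply_adherence_boost(0.95, 0.15), "[Cc]lip")
  expect_identical(out, 1)
  expect_identical(apply_adherence_boost(0.40, 0.15, ramp_fraction = 0), 0.40)
})

test_that("diagnostics count true and false positive treatments separately", {
  out <- apply_diagnostic(1000, 3000, coverage = 0.8, detection_prob = 0.85,
                          specificity = 0.95)
  expect_equal(out$diagnosed_treated, 680, tolerance = 1e-12)
  expect_equal(out$false_positive_treatments, 3000 * 0.8 * 0.05,
               tolerance = 1e-12)
  none <- apply_diagnostic(1000, 3000, 0.8, 0.85, specificity = 1)
  expect_identical(none$false_positive_treatments, 0)
})

test_that("mechanism outputs stay within bounds on random inputs", {
  withr::with_seed(99, {
    for (i in 1:200) {
      cov <- runif(1); eff <- runif(1); base <- runif(1); elig <- runif(1)
      expect_gte(apply_incidence_reduction(runif(1, 0, 4), cov, eff, elig), 0)
      expect_true(is_frac <- {
        v <- apply_mortality_reduction(runif(1), cov, eff); v >= 0 && v <= 1
      })
      v <- suppressWarnings(apply_coverage_expansion(base, cov, "expand"))
      expect_true(v >= 0 && v <= 1)
      v <- suppressWarnings(apply_adherence_boost(base, cov, eff))
      expect_true(v >= 0 && v <= 1)
      expect_gte(apply_second_line(runif(1, 0, 1e4), cov, eff), 0)
    }
  })
})
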