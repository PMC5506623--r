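{
  "innovation_id": "odon",
  "condition_id": "obstructed_labor",
  "mechanism": "coverage_expansion",
  "launch_year": 2018,
  "ramp_years": 5,
  "unit_cost": 25,
  "units_per_person_covered": 1,
  "introduction_cost": 0,
  "peak_coverage": {"home": null, "clinic": 0.40, "hospital": null},
  "effectiveness": {"home": null, "clinic": 0.72, "hospital": 0.81},
  "market_behavior": "expand",
  "eligible_population_filter": null,
  "notes": "Simple assisted-delivery device expanding coverage of assisted vaginal delivery in clinic settings; effectiveness similar to existing instrumented delivery; hospital effectiveness recorded but no hospital introduction modeled."
}
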