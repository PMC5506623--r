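{
  "innovation_id": "rr_monitor",
  "condition_id": "pneumonia",
  "mechanism": "diagnostic_improvement",
  "launch_year": 2015,
  "ramp_years": 5,
  "unit_cost": 50,
  "units_per_person_covered": 1000,
  "introduction_cost": 0,
  "peak_coverage": {"home": null, "clinic": 0.50, "hospital": 0.60},
  "effectiveness": {"home": null, "clinic": 0.80, "hospital": 0.80},
  "market_behavior": "expand",
  "eligible_population_filter": null,
  "specificity": 0.95,
  "notes": "Improved respiratory rate monitor for diagnosing childhood pneumonia in clinics and hospitals; effectiveness based on respiratory-rate counting and chest-wall indrawing evidence; durable device assumed to perform 1000 screens per device-year."
}
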