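{
  "innovation_id": "pulse_oximeter",
  "condition_id": "pneumonia",
  "mechanism": "diagnostic_improvement",
  "launch_year": 2015,
  "ramp_years": 5,
  "unit_cost": 40,
  "units_per_person_covered": 1000,
  "introduction_cost": 0,
  "peak_coverage": {"home": null, "clinic": 0.70, "hospital": 0.80},
  "effectiveness": {"home": null, "clinic": 0.85, "hospital": 0.85},
  "market_behavior": "expand",
  "eligible_population_filter": null,
  "specificity": 0.95,
  "notes": "Portable pulse oximeter detecting low oxygen saturation in children presenting at clinics and hospitals; effectiveness is detection probability; durable device assumed to perform 1000 screens per device-year."
}
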