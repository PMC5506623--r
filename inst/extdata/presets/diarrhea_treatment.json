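{
  "innovation_id": "diarrhea_treatment",
  "condition_id": "diarrhea",
  "mechanism": "adherence_boost",
  "launch_year": 2018,
  "ramp_years": 5,
  "unit_cost": 0.50,
  "units_per_person_covered": 1,
  "introduction_cost": 0,
  "peak_coverage": {"home": 0.80, "clinic": null, "hospital": null},
  "effectiveness": {"home": 0.15, "clinic": null, "hospital": null},
  "market_behavior": "expand",
  "eligible_population_filter": null,
  "notes": "New severe-diarrhea treatments used concurrently with ORS; not effective at reducing mortality in isolation, but raise ORS coverage by 15 percentage points (stored in effectiveness as a fraction); cost based on ORS."
}
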