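{
  "innovation_id": "water_chlorinator",
  "condition_id": "diarrhea",
  "mechanism": "incidence_reduction",
  "launch_year": 2015,
  "ramp_years": 5,
  "unit_cost": 70,
  "units_per_person_covered": 1000,
  "introduction_cost": 0,
  "peak_coverage": {"home": 0.25, "clinic": null, "hospital": null},
  "effectiveness": {"home": 0.84, "clinic": null, "hospital": null},
  "market_behavior": "expand",
  "eligible_population_filter": "community_water",
  "notes": "Automated batch chlorinator for small-scale water treatment; 84% reduction in diarrhea incidence among covered users of community water sources; one unit serves 1000 people."
}
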