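{
  "innovation_id": "oxytocin_new_formulation",
  "condition_id": "pph",
  "mechanism": "coverage_expansion",
  "launch_year": 2022,
  "ramp_years": 5,
  "unit_cost": 0.50,
  "units_per_person_covered": 1,
  "introduction_cost": 0,
  "peak_coverage": {"home": 0.25, "clinic": 0.20, "hospital": 0.10},
  "effectiveness": {"home": 0.40, "clinic": 0.45, "hospital": 0.45},
  "market_behavior": "expand",
  "eligible_population_filter": null,
  "notes": "Heat-stable, non-injectable oxytocin formulations expand the uterotonic market without replacing conventional oxytocin; effectiveness equals the conventional comparator; cost assumed similar to misoprostol."
}
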