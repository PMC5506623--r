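{
  "innovation_id": "chlorhexidine",
  "condition_id": "neonatal_sepsis",
  "mechanism": "mortality_reduction",
  "launch_year": 2015,
  "ramp_years": 5,
  "unit_cost": 0.36,
  "units_per_person_covered": 1,
  "introduction_cost": 0,
  "peak_coverage": {"home": 0.55, "clinic": null, "hospital": null},
  "effectiveness": {"home": 0.23, "clinic": null, "hospital": null},
  "market_behavior": "expand",
  "eligible_population_filter": "home_births",
  "notes": "Umbilical cord antiseptic for home births; effectiveness is a 23% reduction in neonatal mortality from low-resource meta-analysis data; cost from the UNICEF supply catalog."
}
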