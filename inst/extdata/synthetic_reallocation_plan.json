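{
  "disinvestments": [
    {"id": "xray_spine", "fraction_stopped": 1.0, "releasable_cost_fraction": 1.0},
    {"id": "therapeutic_injections", "fraction_stopped": 1.0, "releasable_cost_fraction": 1.0},
    {"id": "mri_outside_guidelines", "fraction_stopped": 1.0, "releasable_cost_fraction": 1.0}
  ],
  "reinvestments": [
    {"id": "digital_support", "name": "Digital back-pain support service", "n_treated": 10000, "fixed_cost": 0, "variable_cost_per_person": 2, "qaly_per_person": 0.07, "evidence_category": "benefit", "provider": "community"},
    {"id": "back_pain_classes", "name": "Community back-pain classes", "n_treated": 3000, "fixed_cost": 0, "variable_cost_per_person": 50, "qaly_per_person": 0.67, "evidence_category": "benefit", "provider": "community"},
    {"id": "case_management", "name": "Case management for complex back pain", "n_treated": 200, "fixed_cost": 0, "variable_cost_per_person": 500, "qaly_per_person": 1.9, "evidence_category": "benefit", "provider": "community"}
  ],
  "budget_mode": "fixed_envelope",
  "envelope": 4500000
}
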