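{
  "label": "frobnicate",
  "parameters": {
    "n_users_initial": 55000,
    "annual_nonfatal_od": 0.069,
    "annual_fatal_od": 0.0188,
    "annual_treatment_entry": 0.15,
    "annual_relapse": 0.5,
    "uses_per_day": 4,
    "step_minutes": 30,
    "ops_capacity": 0,
    "ops_hours_per_day": 20,
    "ops_od_proportion": 1,
    "ops_referral_prob": 0,
    "od_referral_prob": 0,
    "new_entrants_per_day": 3,
    "horizon_days": 365,
    "n_replicates": 3000,
    "base_visit_prob": 0.67
  },
  "profile_source": "synthetic (seed 1)",
  "n_replicates": 100,
  "seed": 1,
  "package": "opsim",
  "version": "0.1.0"
}
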