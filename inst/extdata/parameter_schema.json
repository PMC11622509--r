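{
  "mean_age": {
    "domain": "count",
    "length": 1,
    "required": true
  },
  "horizon_years": {
    "domain": "count",
    "length": 1,
    "required": true
  },
  "cycle_years": {
    "domain": "count",
    "length": 1,
    "required": true
  },
  "discount_rate": {
    "domain": "fraction",
    "length": 1,
    "required": true
  },
  "base_population": {
    "domain": "count",
    "length": 1,
    "required": true
  },
  "dispatcher_miss": {
    "domain": "probability",
    "length": 1,
    "required": true
  },
  "logistic_miss_base": {
    "domain": "probability",
    "length": 1,
    "required": true
  },
  "logistic_miss_slope": {
    "domain": "fraction",
    "length": 1,
    "required": true
  },
  "ivt_rate_msu": {
    "domain": "probability",
    "length": 1,
    "required": true
  },
  "overhead": {
    "domain": "fraction",
    "length": 1,
    "required": true
  },
  "depreciation_years": {
    "domain": "count",
    "length": 1,
    "required": true
  },
  "max_operational_days": {
    "domain": "count",
    "length": 1,
    "required": true
  },
  "wtp": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "psa_iterations": {
    "domain": "count",
    "length": 1,
    "required": true
  },
  "incidence_per_100k": {
    "domain": "rate",
    "length": 4,
    "required": true
  },
  "ems_contact_rate": {
    "domain": "probability",
    "length": 1,
    "required": true
  },
  "msu_criteria_rate": {
    "domain": "probability",
    "length": 1,
    "required": true
  },
  "circadian_weights": {
    "domain": "simplex",
    "length": 24,
    "required": true
  },
  "window_start_hour": {
    "domain": "count",
    "length": 1,
    "required": true
  },
  "capital_vehicle": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "capital_ct": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "capital_equipment": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "running_annual": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "paramedic_hourly": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "neurologist_hourly": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "radiology_tech_hourly": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "remote_neurologist_hourly": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "remote_radiologist_annual": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "project_manager_annual": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "project_manager_fte": {
    "domain": "fraction",
    "length": 1,
    "required": true
  },
  "training_annual": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "deployment_variable_cost": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "conventional_transport_cost": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "msu_transport_cost": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "secondary_transfer_cost": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "secondary_transfer_prob": {
    "domain": "probability",
    "length": 1,
    "required": true
  },
  "acute_cost_by_mrs": {
    "domain": "cost",
    "length": 7,
    "required": true
  },
  "acute_cost_tia": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "acute_cost_hemorrhagic": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "acute_cost_mimic": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "lt_hc_annual_by_mrs": {
    "domain": "cost",
    "length": 6,
    "required": true
  },
  "lt_nursing_insurance_by_mrs": {
    "domain": "cost",
    "length": 6,
    "required": true
  },
  "lt_nursing_family_by_mrs": {
    "domain": "cost",
    "length": 6,
    "required": true
  },
  "gross_annual_wage": {
    "domain": "cost",
    "length": 1,
    "required": true
  },
  "employment_rate": {
    "domain": "probability",
    "length": 1,
    "required": true
  },
  "ability_to_work_by_mrs": {
    "domain": "fraction",
    "length": 6,
    "required": true
  },
  "retirement_age": {
    "domain": "count",
    "length": 1,
    "required": true
  },
  "mrs_entry_conventional": {
    "domain": "simplex",
    "length": 7,
    "required": true
  },
  "mrs_entry_msu": {
    "domain": "simplex",
    "length": 7,
    "required": true
  },
  "utilities_by_mrs": {
    "domain": "probability",
    "length": 6,
    "required": true
  },
  "mortality_by_mrs": {
    "domain": "probability",
    "length": 6,
    "required": true
  },
  "recurrence_by_year": {
    "domain": "probability",
    "length": 5,
    "required": true
  },
  "nonis_utility": {
    "domain": "probability",
    "length": 1,
    "required": true
  },
  "service_time_hours": {
    "domain": "count",
    "length": 1,
    "required": true
  }
}
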