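{
  "model_id": "HEMA",
  "name": "Hip fracture Estimator of Mortality Amsterdam",
  "link": "P(30-day death) = 1 / (1 + exp(intercept - slope * score))",
  "intercept": 3.823,
  "slope": 1,
  "rules": [
    {"variable": "age", "condition": ">=85", "points": 1},
    {"variable": "in_hospital_fracture", "condition": "yes", "points": 2},
    {"variable": "malnutrition", "condition": "yes", "points": 2},
    {"variable": "myocardial_infarction", "condition": "yes", "points": 1},
    {"variable": "congestive_heart_failure", "condition": "yes", "points": 1},
    {"variable": "pneumonia", "condition": "yes", "points": 2},
    {"variable": "renal_disease", "condition": "yes", "points": 1},
    {"variable": "malignancy", "condition": "yes", "points": 1.5},
    {"variable": "serum_urea", "condition": ">9 mmol/L", "points": 0.5}
  ],
  "risk_groups": {
    "low": "score <= 1",
    "intermediate": "1.5 <= score <= 2",
    "high": "score >= 2.5"
  }
}
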