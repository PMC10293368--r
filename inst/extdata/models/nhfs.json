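{
  "model_id": "NHFS",
  "name": "Nottingham Hip Fracture Score",
  "link": "P(30-day death) = 1 / (1 + exp(intercept - slope * score))",
  "intercept": 5.0122,
  "slope": 0.481,
  "rules": [
    {"variable": "age", "condition": "<66", "points": 0},
    {"variable": "age", "condition": "66-85", "points": 3},
    {"variable": "age", "condition": ">=86", "points": 4},
    {"variable": "sex", "condition": "male", "points": 1},
    {"variable": "haemoglobin", "condition": "<=10 g/dL", "points": 1},
    {"variable": "cognitive_impairment", "condition": "yes", "points": 1},
    {"variable": "institutional_residence", "condition": "yes", "points": 1},
    {"variable": "n_comorbidities", "condition": ">=2", "points": 1},
    {"variable": "malignancy", "condition": "yes", "points": 1}
  ],
  "risk_groups": {
    "low": "score <= 3",
    "intermediate": "4 <= score <= 5",
    "high": "score >= 6"
  }
}
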