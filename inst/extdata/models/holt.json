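{
  "model_id": "HOLT",
  "name": "Holt et al. (Scottish Hip Fracture Audit)",
  "link": "P(30-day death) = 1 / (1 + exp(intercept - slope * score))",
  "intercept": 4.79,
  "slope": 1,
  "rules": [
    {"variable": "age", "condition": "<60", "points": 0},
    {"variable": "age", "condition": "60-69", "points": 0.58},
    {"variable": "age", "condition": "70-79", "points": 1.24},
    {"variable": "age", "condition": "80-89", "points": 1.74},
    {"variable": "age", "condition": ">=90", "points": 1.96},
    {"variable": "asa", "condition": "1-2", "points": 0},
    {"variable": "asa", "condition": "3", "points": 0.8},
    {"variable": "asa", "condition": "4-5", "points": 1.62},
    {"variable": "sex", "condition": "male", "points": 0},
    {"variable": "sex", "condition": "female", "points": -0.65},
    {"variable": "prefracture_residence", "condition": "own_home", "points": 0},
    {"variable": "prefracture_residence", "condition": "long_term_care", "points": 0.53},
    {"variable": "prefracture_residence", "condition": "rehabilitation", "points": 0.53},
    {"variable": "prefracture_residence", "condition": "acute_hospital_ward", "points": 0.59},
    {"variable": "prefracture_mobility", "condition": "no_aids", "points": 0},
    {"variable": "prefracture_mobility", "condition": "one_aid", "points": -0.02},
    {"variable": "prefracture_mobility", "condition": "two_aids_frame", "points": 0.07},
    {"variable": "prefracture_mobility", "condition": "requires_accompaniment", "points": 0.24},
    {"variable": "prefracture_mobility", "condition": "unable_to_walk", "points": 0.45},
    {"variable": "fracture_type", "condition": "intracapsular", "points": 0},
    {"variable": "fracture_type", "condition": "extracapsular", "points": 0.12},
    {"variable": "fracture_type", "condition": "subtrochanteric", "points": 0.28},
    {"variable": "fracture_type", "condition": "pathological", "points": 1.32}
  ],
  "risk_groups": {
    "low": "score < 1",
    "intermediate": "1 <= score <= 2",
    "high": "score > 2"
  }
}
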