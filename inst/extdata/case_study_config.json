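{
  "graphs": {
    "primary": "case_study_mdag_a.json",
    "alternatives": {
      "b": "case_study_mdag_b.json"
    }
  },
  "estimand": {
    "target": "regression_coefficient",
    "outcome": "Y",
    "exposure": "X",
    "covariates": [
      "C",
      "Z"
    ]
  },
  "roles": {
    "C": "C",
    "Z": "Z",
    "X": "X",
    "Y": "Y",
    "M_X": "M_X",
    "M_Y": "M_Y",
    "M_Z": "M_Z"
  },
  "deltas": [
    0.56,
    2.12,
    4.92
  ],
  "generator": {
    "n": 4882,
    "variant": "a"
  },
  "imputation": {
    "m": 10,
    "cycles": 5
  },
  "seed": 20230213
}
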