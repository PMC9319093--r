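[
  {"metric": "errat",             "direction": "higher", "thresholds": [100, 99, 98],          "weight": 1},
  {"metric": "verify3d",          "direction": "higher", "thresholds": [73, 67, 61],           "weight": 1},
  {"metric": "prove",             "direction": "lower",  "thresholds": [2.8, 3.2, 3.6],        "weight": 1},
  {"metric": "rama_core",         "direction": "higher", "thresholds": [94.4, 93.7, 93.0],     "weight": 0.5},
  {"metric": "rama_disallowed",   "direction": "lower",  "thresholds": [0.0, 0.4, 0.8],        "weight": 0.5},
  {"metric": "labelled_residues", "direction": "lower",  "thresholds": [3, 5, 7],              "weight": 1},
  {"metric": "rwplus",            "direction": "lower",  "thresholds": [-79000, -78250, -77500], "weight": 1},
  {"metric": "molprobity",        "direction": "lower",  "thresholds": [1.0, 1.2, 1.4],        "weight": 1},
  {"metric": "rosetta",           "direction": "lower",  "thresholds": [-750, -675, -600],     "weight": 1},
  {"metric": "dfire",             "direction": "lower",  "thresholds": [-649, -641, -633],     "weight": 1},
  {"metric": "goap",              "direction": "lower",  "thresholds": [-37200, -36000, -34800], "weight": 1},
  {"metric": "opus_psp",          "direction": "lower",  "thresholds": [-5770, -5650, -5530],  "weight": 1},
  {"metric": "global_quality",    "direction": "higher", "thresholds": [0.26, 0.24, 0.22],     "weight": 1}
]
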