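{
  "provenance": "period1-posterior (2010, hoary bat)",
  "entries": {
    "beta0": {"family": "normal", "mean": 0.15, "sd": 1.15},
    "a": {"family": "normal", "mean": -0.68, "sd": 1.52},
    "b": {"family": "normal", "mean": 4.32, "sd": 1.94},
    "beta_elevation": {"family": "normal", "mean": -0.52, "sd": 0.29},
    "beta_precipitation": {"family": "normal", "mean": -0.41, "sd": 0.30},
    "beta_roughness": {"family": "normal", "mean": -0.08, "sd": 0.21},
    "beta_forest": {"family": "normal", "mean": 0.64, "sd": 0.26}
  }
}
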