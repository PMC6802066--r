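{
  "provenance": "period1-posterior (2010, little brown bat)",
  "entries": {
    "beta0": {"family": "normal", "mean": 3.53, "sd": 1.62},
    "a": {"family": "normal", "mean": 0.14, "sd": 1.57},
    "b": {"family": "normal", "mean": 3.49, "sd": 1.76},
    "beta_elevation": {"family": "normal", "mean": -0.29, "sd": 0.27},
    "beta_precipitation": {"family": "normal", "mean": 1.59, "sd": 0.97},
    "beta_roughness": {"family": "normal", "mean": 0.00, "sd": 0.29},
    "beta_forest": {"family": "normal", "mean": 0.46, "sd": 0.34}
  }
}
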