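[
  {
    "name": "F18",
    "beta_yield": 0.967,
    "half_life": 109.8,
    "e_max": 633.5,
    "e_mean": 249.3,
    "range_max_water": 2.4,
    "range_mean_water": 0.6
  },
  {
    "name": "Ga68",
    "beta_yield": 0.880,
    "half_life": 67.6,
    "e_max": 1899.1,
    "e_mean": 836.0,
    "range_max_water": 9.2,
    "range_mean_water": 3.5
  },
  {
    "name": "Cu64",
    "beta_yield": 0.174,
    "half_life": 762.0,
    "e_max": 653.1,
    "e_mean": 278.0,
    "range_max_water": 2.5,
    "range_mean_water": 0.7
  }
]
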