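[
  {"name": "RICA", "x_mm": 25, "y_mm": 10, "psi_rad": 0},
  {"name": "LICA", "x_mm": -25, "y_mm": 10, "psi_rad": 0},
  {"name": "RVA", "x_mm": 10, "y_mm": -10, "psi_rad": 0},
  {"name": "LVA", "x_mm": -10, "y_mm": -10, "psi_rad": 0}
]
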