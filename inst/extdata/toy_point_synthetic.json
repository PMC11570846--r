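{
  "label": "toy-point",
  "radionuclide": "toy",
  "lambda_cGy_per_h_per_U": 1,
  "active_length_mm": null,
  "geometry_model": "point",
  "provenance": "Synthetic toy source: unit dose-rate constant, g = F = 1, point geometry. For analytic checks only.",
  "radial_dose": [
    [0.1, 1],
    [1, 1],
    [10, 1]
  ]
}
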