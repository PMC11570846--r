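{
  "label": "ir192-generic-synthetic",
  "radionuclide": "Ir-192",
  "lambda_cGy_per_h_per_U": 1.108,
  "active_length_mm": 3.5,
  "geometry_model": "line",
  "provenance": "Synthetic consensus-style TG-43 tables for a generic miniature HDR Ir-192 line source. Not the characterization of any commercial source model; assembled to have realistic smooth shape for testing and simulation.",
  "radial_dose": [
    [0.25, 0.99],
    [0.5, 0.996],
    [1, 1],
    [1.5, 1.003],
    [2, 1.004],
    [3, 1.004],
    [4, 1.001],
    [5, 0.996],
    [6, 0.988],
    [8, 0.966],
    [10, 0.935]
  ],
  "anisotropy": {
    "r_cm": [0.5, 1, 2, 3, 5],
    "theta_deg": [0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120, 130, 140, 150, 160, 170, 180],
    "F": [
      [0.775, 0.8342, 0.8848, 0.9258, 0.9567, 0.978, 0.991, 0.9975, 0.9997, 1, 0.9997, 0.9975, 0.991, 0.978, 0.9567, 0.9258, 0.8848, 0.8342, 0.775],
      [0.77, 0.8305, 0.8823, 0.9241, 0.9557, 0.9775, 0.9908, 0.9974, 0.9997, 1, 0.9997, 0.9974, 0.9908, 0.9775, 0.9557, 0.9241, 0.8823, 0.8305, 0.77],
      [0.76, 0.8231, 0.8772, 0.9208, 0.9538, 0.9765, 0.9904, 0.9973, 0.9997, 1, 0.9997, 0.9973, 0.9904, 0.9765, 0.9538, 0.9208, 0.8772, 0.8231, 0.76],
      [0.75, 0.8158, 0.872, 0.9175, 0.9518, 0.9755, 0.99, 0.9972, 0.9997, 1, 0.9997, 0.9972, 0.99, 0.9755, 0.9518, 0.9175, 0.872, 0.8158, 0.75],
      [0.73, 0.801, 0.8618, 0.9109, 0.948, 0.9736, 0.9892, 0.997, 0.9997, 1, 0.9997, 0.997, 0.9892, 0.9736, 0.948, 0.9109, 0.8618, 0.801, 0.73]
    ]
  }
}
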