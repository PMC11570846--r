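{
  "label": "co60-generic-synthetic",
  "radionuclide": "Co-60",
  "lambda_cGy_per_h_per_U": 1.087,
  "active_length_mm": 3.5,
  "geometry_model": "line",
  "provenance": "Synthetic consensus-style TG-43 tables for a generic miniature HDR Co-60 line source. Not the characterization of any commercial source model; assembled to have realistic smooth shape for testing and simulation.",
  "radial_dose": [
    [0.25, 1.006],
    [0.5, 1.003],
    [1, 1],
    [1.5, 0.996],
    [2, 0.992],
    [3, 0.982],
    [4, 0.971],
    [5, 0.958],
    [6, 0.945],
    [8, 0.917],
    [10, 0.887]
  ],
  "anisotropy": {
    "r_cm": [0.5, 1, 2, 3, 5],
    "theta_deg": [0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120, 130, 140, 150, 160, 170, 180],
    "F": [
      [0.9175, 0.9392, 0.9578, 0.9728, 0.9841, 0.9919, 0.9967, 0.9991, 0.9999, 1, 0.9999, 0.9991, 0.9967, 0.9919, 0.9841, 0.9728, 0.9578, 0.9392, 0.9175],
      [0.915, 0.9374, 0.9565, 0.972, 0.9836, 0.9917, 0.9966, 0.999, 0.9999, 1, 0.9999, 0.999, 0.9966, 0.9917, 0.9836, 0.972, 0.9565, 0.9374, 0.915],
      [0.91, 0.9337, 0.9539, 0.9703, 0.9827, 0.9912, 0.9964, 0.999, 0.9999, 1, 0.9999, 0.999, 0.9964, 0.9912, 0.9827, 0.9703, 0.9539, 0.9337, 0.91],
      [0.905, 0.93, 0.9514, 0.9687, 0.9817, 0.9907, 0.9962, 0.9989, 0.9999, 1, 0.9999, 0.9989, 0.9962, 0.9907, 0.9817, 0.9687, 0.9514, 0.93, 0.905],
      [0.9, 0.9263, 0.9488, 0.967, 0.9807, 0.9902, 0.996, 0.9989, 0.9999, 1, 0.9999, 0.9989, 0.996, 0.9902, 0.9807, 0.967, 0.9488, 0.9263, 0.9]
    ]
  }
}
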