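{
  "grid_shape": [14, 64, 64],
  "in_plane_spacing_mm": 3.6458,
  "slice_thickness_mm": 3.3,
  "background_activity": 0.08,
  "noise_sd": 0.004,
  "suvmax_reference": 10.0,
  "reference": {
    "amplitude": 1.0,
    "sigma_mm": 9.0,
    "row_frac": 0.5,
    "col_frac": 0.12
  },
  "malignant": {
    "n_foci": [3, 5],
    "primary_amplitude": [0.55, 0.95],
    "stack_fraction": [0.4, 0.95],
    "sigma_mm": [3.0, 5.0],
    "offset_frac": [0.4, 0.7],
    "drift_mag_mm": [1.5, 3.0],
    "radius_mm": [8, 14]
  },
  "benign": {
    "n_foci": [1, 1],
    "primary_amplitude": [0.2, 0.34],
    "stack_fraction": [0, 0],
    "sigma_mm": [5.5, 7.5],
    "offset_frac": [0, 0.1],
    "drift_mag_mm": [0, 0],
    "radius_mm": [8, 14]
  }
}
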