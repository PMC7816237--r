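{
  "name": "FAIR-CS3_S",
  "cardiac_phase": "systole",
  "accel_method": "compressed_sensing",
  "accel_factor": 3,
  "fov_mm": [300, 300],
  "matrix": [150, 150],
  "pixel_mm": [2, 2],
  "slice_mm": 10,
  "tr_ms": 2.2,
  "te_ms": 1.1,
  "flip_deg": 50,
  "nominal_ti_ms": 1000,
  "control_slab_mm": 30,
  "rest_period_ms": 90
}
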