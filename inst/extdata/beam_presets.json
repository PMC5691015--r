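{
  "6": {
    "nominal": 6,
    "r50_mm": 23.5,
    "rp_mm": 30,
    "surface_fraction": 0.8,
    "dmax_mm": 13,
    "tail_percent": 1.1,
    "grid_max_mm": 60
  },
  "9": {
    "nominal": 9,
    "r50_mm": 36.0,
    "rp_mm": 46,
    "surface_fraction": 0.84,
    "dmax_mm": 20,
    "tail_percent": 1.4,
    "grid_max_mm": 76
  },
  "12": {
    "nominal": 12,
    "r50_mm": 48.5,
    "rp_mm": 62,
    "surface_fraction": 0.88,
    "dmax_mm": 27,
    "tail_percent": 1.8,
    "grid_max_mm": 92
  },
  "15": {
    "nominal": 15,
    "r50_mm": 63.4,
    "rp_mm": 77,
    "surface_fraction": 0.92,
    "dmax_mm": 33,
    "tail_percent": 2.2,
    "grid_max_mm": 107
  }
}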