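{
  "schema_version": 1,
  "patient_id": "demo-01",
  "side": "right",
  "timepoint": "pre",
  "calibration": {
    "marker_a": [500, 100],
    "marker_b": [500, 300],
    "known_distance_mm": 100
  },
  "landmarks": {
    "femoral_head_center": [500, 100],
    "plateau_medial_edge": [570, 900],
    "plateau_lateral_edge": [430, 900],
    "ankle_center": [540, 1700]
  },
  "polylines": {
    "medial_cortex": [
      [566, 900],
      [566, 1300],
      [566, 1700]
    ],
    "lateral_cortex": [
      [434, 900],
      [434, 1300],
      [434, 1700]
    ]
  }
}
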