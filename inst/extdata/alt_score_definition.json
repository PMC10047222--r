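{
  "decision_cutoff": 3,
  "items": [
    {"feature": "septation_thickness", "type": "threshold", "cutoff": 1.3, "direction": "greater"},
    {"feature": "stir_discrepancy", "type": "binary", "positive_state": 1},
    {"feature": "diameter_y", "type": "threshold", "cutoff": 39.5, "direction": "greater"},
    {"feature": "contrast_enhancement", "type": "binary", "positive_state": 1},
    {"feature": "diameter_x", "type": "threshold", "cutoff": 125.5, "direction": "greater"}
  ]
}
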