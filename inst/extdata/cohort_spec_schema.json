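{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cohort_spec",
  "description": "Generator specification for a synthetic two-group (B/ALT) patient cohort.",
  "type": "object",
  "required": ["n_B", "n_ALT", "features"],
  "properties": {
    "n_B": {"type": "integer", "minimum": 0},
    "n_ALT": {"type": "integer", "minimum": 0},
    "correlation": {
      "description": "Latent Gaussian copula correlation matrix (unit diagonal, PSD); null means independence.",
      "type": ["array", "null"],
      "items": {"type": "array", "items": {"type": "number"}}
    },
    "features": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "kind"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "kind": {"enum": ["binary", "categorical", "continuous"]},
          "prevalence": {
            "type": "object",
            "properties": {
              "B": {"type": "number", "minimum": 0, "maximum": 1},
              "ALT": {"type": "number", "minimum": 0, "maximum": 1}
            }
          },
          "levels": {"type": "array", "items": {"type": "string"}},
          "probs": {
            "type": "object",
            "properties": {
              "B": {"type": "array", "items": {"type": "number", "minimum": 0}},
              "ALT": {"type": "array", "items": {"type": "number", "minimum": 0}}
            }
          },
          "family": {"enum": ["truncnorm", "lognormal"]},
          "mean": {"type": "object", "properties": {"B": {"type": "number"}, "ALT": {"type": "number"}}},
          "sd": {
            "type": "object",
            "properties": {
              "B": {"type": "number", "exclusiveMinimum": 0},
              "ALT": {"type": "number", "exclusiveMinimum": 0}
            }
          },
          "lower": {"type": "number"},
          "upper": {"type": "number"}
        }
      }
    }
  }
}
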