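{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "wareamd risk report",
  "type": "object",
  "required": [
    "subject_id", "genetic_risk", "overall_risk", "zone",
    "percentile_population", "percentile_cases",
    "relative_risk_population", "relative_risk_cases",
    "window_fractions_population", "window_fractions_cases",
    "zone_config", "panel_provenance", "inputs_echo"
  ],
  "properties": {
    "subject_id": { "type": "string" },
    "genetic_risk": { "type": "number", "exclusiveMinimum": 0 },
    "overall_risk": { "type": "number", "exclusiveMinimum": 0 },
    "zone": { "type": "string", "enum": ["low", "intermediate", "high"] },
    "percentile_population": { "type": "number", "minimum": 0, "maximum": 1 },
    "percentile_cases": { "type": "number", "minimum": 0, "maximum": 1 },
    "relative_risk_population": { "type": "number", "exclusiveMinimum": 0 },
    "relative_risk_cases": { "type": "number", "exclusiveMinimum": 0 },
    "window_fractions_population": { "$ref": "#/definitions/window" },
    "window_fractions_cases": { "$ref": "#/definitions/window" },
    "zone_config": {
      "type": "object",
      "required": ["low_boundary", "high_boundary"],
      "properties": {
        "low_boundary": { "type": "number", "exclusiveMinimum": 0 },
        "high_boundary": { "type": "number", "exclusiveMinimum": 0 }
      }
    },
    "panel_provenance": { "type": "string" },
    "inputs_echo": {
      "type": "object",
      "required": ["genotypes"],
      "properties": {
        "smoking": { "type": "string", "enum": ["yes", "no"] },
        "familiarity": { "type": "string", "enum": ["present", "absent"] }
      }
    }
  },
  "definitions": {
    "window": {
      "type": "object",
      "required": ["lower", "equal", "greater", "half_width"],
      "properties": {
        "lower": { "type": "number", "minimum": 0, "maximum": 1 },
        "equal": { "type": "number", "minimum": 0, "maximum": 1 },
        "greater": { "type": "number", "minimum": 0, "maximum": 1 },
        "half_width": { "type": "number", "exclusiveMinimum": 0 }
      }
    }
  }
}
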