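{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Scenario library",
  "description": "Format of the YAML scenario library read by scenario_library(). Each entry names the coverage levers a scenario raises; the incremental/universal levels themselves are applied by the engine.",
  "type": "array",
  "items": {
    "type": "object",
    "additionalProperties": false,
    "required": ["id", "table", "number", "group", "description"],
    "properties": {
      "id": {"type": "string"},
      "table": {"type": "integer"},
      "number": {"type": "integer", "minimum": 1},
      "group": {
        "enum": ["direct", "indirect"],
        "description": "direct = scored on RDS+IVH+NEC deaths; indirect = sepsis+birth asphyxia+LBW"
      },
      "description": {"type": "string"},
      "mode": {
        "enum": ["none", "levers"],
        "description": "none marks the current-care baseline (identity transform)"
      },
      "interventions": {
        "type": "array",
        "items": {"$ref": "#/$defs/lever"}
      },
      "gates": {
        "type": "array",
        "items": {"$ref": "#/$defs/lever"}
      },
      "transfer": {
        "type": "array",
        "items": {"type": "string"},
        "description": "diagnostic gates whose diagnosed cases are referred to the destination setting"
      },
      "delivery_override": {
        "type": "object",
        "description": "replacement delivery mix, percent",
        "required": ["home", "clinic", "hospital"],
        "additionalProperties": {"type": "number", "minimum": 0, "maximum": 100}
      }
    }
  },
  "$defs": {
    "lever": {
      "type": "object",
      "additionalProperties": false,
      "required": ["name", "settings"],
      "properties": {
        "name": {"type": "string"},
        "settings": {
          "type": "array",
          "items": {"enum": ["home", "clinic", "hospital"]},
          "minItems": 1
        }
      }
    }
  }
}
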