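{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Preterm-mortality cohort model parameter set",
  "description": "Configuration accepted by load_parameter_set(). Values are percent or proportions per the top-level units key; every coverage quantity must lie in [0, 100] or [0, 1] accordingly.",
  "type": "object",
  "additionalProperties": false,
  "required": ["units", "population", "subconditions", "diagnostics", "interventions"],
  "properties": {
    "name": {"type": "string"},
    "units": {"enum": ["percent", "proportion"]},
    "coverage_cap": {"type": "number", "minimum": 0},
    "anc_weighting": {"enum": ["anc", "delivery"]},
    "incremental_mode": {"enum": ["additive", "relative"]},
    "population": {
      "type": "object",
      "additionalProperties": false,
      "required": ["n_preterm_births", "delivery_mix", "anc_mix"],
      "properties": {
        "n_preterm_births": {"type": "number", "exclusiveMinimum": 0},
        "delivery_mix": {"$ref": "#/$defs/settingMap"},
        "anc_mix": {"$ref": "#/$defs/settingMap"}
      }
    },
    "subconditions": {
      "type": "array",
      "minItems": 6,
      "maxItems": 6,
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["name", "prevalence", "untreated_cfr"],
        "properties": {
          "name": {"enum": ["RDS", "IVH", "NEC", "sepsis", "birth_asphyxia", "LBW_only"]},
          "prevalence": {"type": "number", "minimum": 0},
          "untreated_cfr": {"type": "number", "minimum": 0}
        }
      }
    },
    "diagnostics": {
      "type": "array",
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["gate", "penetration", "utilization", "efficacy"],
        "properties": {
          "gate": {"enum": ["preterm_labor", "RDS", "IVH", "NEC", "sepsis", "LBW", "birth_asphyxia"]},
          "penetration": {"$ref": "#/$defs/settingMap"},
          "utilization": {"$ref": "#/$defs/settingMap"},
          "efficacy": {"$ref": "#/$defs/settingMap"}
        }
      }
    },
    "interventions": {
      "type": "array",
      "items": {
        "type": "object",
        "additionalProperties": false,
        "required": ["name", "penetration", "utilization", "efficacy"],
        "properties": {
          "name": {"type": "string"},
          "role": {"enum": ["diagnostic", "preventive", "treatment"]},
          "timing": {"enum": ["antenatal", "delivery", "postnatal"]},
          "requires_diagnosis": {"type": "boolean"},
          "gate": {"type": "string", "description": "\"target\" (each target subcondition's own gate) or an explicit gate name"},
          "penetration": {"$ref": "#/$defs/settingMap"},
          "utilization": {"$ref": "#/$defs/settingMap"},
          "efficacy": {
            "type": "object",
            "description": "per-target relative mortality reduction",
            "minProperties": 1,
            "propertyNames": {"enum": ["RDS", "IVH", "NEC", "sepsis", "birth_asphyxia", "LBW_only"]},
            "additionalProperties": {"type": "number", "minimum": 0}
          }
        }
      }
    },
    "transfer": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "destination": {"enum": ["home", "clinic", "hospital"]},
        "probabilities": {
          "type": "array",
          "items": {
            "type": "object",
            "additionalProperties": false,
            "required": ["gate", "origin", "probability"],
            "properties": {
              "gate": {"type": "string"},
              "origin": {"enum": ["home", "clinic"]},
              "probability": {"type": "number", "minimum": 0}
            }
          }
        }
      }
    }
  },
  "$defs": {
    "settingMap": {
      "type": "object",
      "additionalProperties": false,
      "required": ["home", "clinic", "hospital"],
      "properties": {
        "home": {"type": "number", "minimum": 0},
        "clinic": {"type": "number", "minimum": 0},
        "hospital": {"type": "number", "minimum": 0}
      }
    }
  }
}
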