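{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "kb.schema.json",
  "title": "Syncope decision-support knowledge base",
  "type": "object",
  "required": ["version", "questions", "priors", "css", "recommendations"],
  "$defs": {
    "etiology": {
      "enum": ["vasovagal", "orthostatic", "cardiogenic", "neurogenic_loc"]
    },
    "lhrPair": {
      "oneOf": [
        {"type": "null"},
        {
          "type": "object",
          "required": ["lhr_pos", "lhr_neg"],
          "properties": {
            "lhr_pos": {"type": "number", "exclusiveMinimum": 0},
            "lhr_neg": {"type": "number", "exclusiveMinimum": 0}
          }
        }
      ]
    }
  },
  "properties": {
    "version": {"type": "string", "minLength": 1},
    "tie_break_order": {
      "type": "array",
      "items": {"$ref": "#/$defs/etiology"},
      "minItems": 4,
      "maxItems": 4,
      "uniqueItems": true
    },
    "questions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "text", "lhr", "css_input", "prompt_only"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "text": {"type": "string"},
          "lhr": {
            "type": "object",
            "propertyNames": {"$ref": "#/$defs/etiology"},
            "additionalProperties": {"$ref": "#/$defs/lhrPair"}
          },
          "css_input": {"type": "boolean"},
          "prompt_only": {"type": "boolean"},
          "override_for": {
            "oneOf": [{"type": "null"}, {"$ref": "#/$defs/etiology"}]
          },
          "numeric_threshold": {
            "oneOf": [
              {"type": "null"},
              {
                "type": "array",
                "items": {
                  "type": "object",
                  "required": ["value", "unit"],
                  "properties": {
                    "value": {"type": "number"},
                    "unit": {"type": "string"}
                  }
                }
              }
            ]
          }
        }
      }
    },
    "priors": {
      "type": "object",
      "propertyNames": {"$ref": "#/$defs/etiology"},
      "additionalProperties": {
        "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1
      }
    },
    "css": {
      "type": "object",
      "required": ["items", "thresholds"],
      "properties": {
        "items": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["name", "source", "points"],
            "properties": {
              "name": {"type": "string"},
              "source": {"type": "string"},
              "points": {"type": "integer"}
            }
          }
        },
        "thresholds": {
          "type": "object",
          "required": ["low_below", "high_above"],
          "properties": {
            "low_below": {"type": "integer"},
            "high_above": {"type": "integer"}
          }
        }
      }
    },
    "recommendations": {
      "type": "object",
      "required": ["primary", "secondary", "question_specific",
                   "disposition"],
      "properties": {
        "primary": {
          "type": "object",
          "propertyNames": {"$ref": "#/$defs/etiology"},
          "additionalProperties": {"type": "string"}
        },
        "secondary": {
          "type": "object",
          "additionalProperties": {"type": "string"}
        },
        "question_specific": {
          "type": "object",
          "additionalProperties": {"type": "string"}
        },
        "disposition": {
          "type": "object",
          "required": ["low", "intermediate", "high"],
          "additionalProperties": {"type": "string"}
        }
      }
    }
  }
}
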