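{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "record.schema.json",
  "title": "Anonymized syncope evaluation record (one JSON Lines row)",
  "type": "object",
  "required": ["record_id", "timestamp", "answers", "app_top", "css_total",
               "risk_class"],
  "properties": {
    "record_id": {"type": "string"},
    "timestamp": {"type": "string"},
    "answers": {
      "type": "object",
      "additionalProperties": {"enum": ["yes", "no", "unknown"]}
    },
    "user_selected_ddx": {
      "oneOf": [
        {"type": "null"},
        {"enum": ["vasovagal", "orthostatic", "cardiogenic",
                  "neurogenic_loc"]}
      ]
    },
    "app_top": {
      "enum": ["vasovagal", "orthostatic", "cardiogenic", "neurogenic_loc"]
    },
    "css_total": {"type": "integer"},
    "risk_class": {"enum": ["low", "intermediate", "high"]},
    "recommendation_keys": {
      "type": "array",
      "items": {"type": "string"}
    },
    "hypothetical": {"type": "boolean"}
  },
  "additionalProperties": false
}
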