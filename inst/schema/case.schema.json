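{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "case.schema.json",
  "title": "Syncope assessment case file",
  "type": "object",
  "required": ["answers"],
  "properties": {
    "case_id": {"type": "string"},
    "answers": {
      "type": "object",
      "additionalProperties": {"enum": ["yes", "no", "unknown"]}
    },
    "user_selected_ddx": {
      "enum": ["vasovagal", "orthostatic", "cardiogenic", "neurogenic_loc"]
    }
  }
}
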