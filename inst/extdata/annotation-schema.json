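{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "narratime annotated document",
  "type": "object",
  "required": ["doc_id", "events", "assertions"],
  "additionalProperties": false,
  "properties": {
    "doc_id": {"type": "string", "minLength": 1},
    "narrative_text": {"type": "string"},
    "events": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "event_type": {
            "enum": ["stent_implantation", "followup_stent_implantation",
                     "antiplatelet_start", "antiplatelet_stop",
                     "antiplatelet_therapy", "unrelated_surgery",
                     "late_stent_thrombosis", "myocardial_infarction",
                     "er_admission", "death", "other"]
          },
          "label": {"type": "string"},
          "span": {
            "type": "array",
            "items": {"type": "integer", "minimum": 0},
            "minItems": 2, "maxItems": 2,
            "description": "0-based half-open [start, end) character interval"
          }
        }
      }
    },
    "assertions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["subject", "relation", "object"],
        "additionalProperties": false,
        "properties": {
          "subject": {"type": "string"},
          "relation": {
            "enum": ["BEFORE", "AFTER", "EQUAL", "STARTS", "FINISHES",
                     "CONTAINS", "DURING"]
          },
          "object": {
            "type": "object",
            "oneOf": [
              {"required": ["event"], "properties": {"event": {"type": "string"}}},
              {"required": ["time"], "properties": {"time": {"type": "string"}}}
            ]
          },
          "offset": {
            "type": "string",
            "description": "duration expression; BEFORE/AFTER only"
          },
          "relation_granularity": {
            "enum": ["minute", "hour", "day", "month", "year"]
          },
          "asserted": {"type": "boolean", "default": true}
        }
      }
    },
    "timestamps": {
      "type": "object",
      "description": "event id -> start/end temporal expressions",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": false,
        "properties": {
          "start": {"type": "string"},
          "end": {"type": "string"}
        }
      }
    },
    "durations": {
      "type": "object",
      "description": "event id -> duration expression",
      "additionalProperties": {"type": "string"}
    },
    "metadata": {"type": "object"}
  }
}
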