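{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "adesignal signal report",
  "type": "object",
  "required": ["table", "excluded", "odds_ratio", "ci_low", "ci_high",
               "p_value", "level", "flags", "config"],
  "properties": {
    "table": {
      "type": "object",
      "required": ["a", "b", "c", "d"],
      "properties": {
        "a": {"type": "integer", "minimum": 0},
        "b": {"type": "integer", "minimum": 0},
        "c": {"type": "integer", "minimum": 0},
        "d": {"type": "integer", "minimum": 0}
      }
    },
    "excluded": {"type": "object"},
    "odds_ratio": {"type": ["number", "null"]},
    "ci_low": {"type": ["number", "null"]},
    "ci_high": {"type": ["number", "null"]},
    "p_value": {"type": ["number", "null"]},
    "level": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
    "flags": {"type": "array", "items": {"type": "string"}},
    "config": {"type": "object"}
  }
}
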