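{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "nephroplan opening report",
  "type": "object",
  "required": ["min_opening_margin_mm", "min_tract_distance_mm", "status_text", "per_margin"],
  "properties": {
    "min_opening_margin_mm": {"type": ["number", "null"]},
    "min_tract_distance_mm": {"type": "number", "minimum": 0},
    "status_text": {"type": "string", "pattern": "^(Open|Not open) with [0-9.]+ mm margin$"},
    "per_margin": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["margin_mm", "open", "opening_voxel_count"],
        "properties": {
          "margin_mm": {"type": "number", "exclusiveMinimum": 0},
          "open": {"type": "boolean"},
          "opening_voxel_count": {"type": "integer", "minimum": 0},
          "opening_centroid_mm": {"type": "array", "minItems": 3, "maxItems": 3, "items": {"type": "number"}},
          "opening_extent_mm": {"type": "number", "minimum": 0}
        }
      }
    }
  }
}
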