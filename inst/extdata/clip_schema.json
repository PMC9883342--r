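{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "handtrack clip annotation / prediction format (handtrack-clip-v1)",
  "description": "One JSON object per clip. Coordinates are 0-based pixel centers (x right, y down); boxes are half-open [x0,x1) x [y0,y1). Unknown fields are preserved on round-trip.",
  "type": "object",
  "required": ["clip_id", "fps", "frames"],
  "properties": {
    "format": {"const": "handtrack-clip-v1"},
    "clip_id": {"type": "string"},
    "fps": {"type": "number", "exclusiveMinimum": 0},
    "frames": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["frame_index", "hands"],
        "properties": {
          "frame_index": {"type": "integer", "description": "strictly increasing across the frames array"},
          "image": {"type": ["string", "null"], "description": "frame image path relative to the annotation file"},
          "hands": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["box", "handedness", "keypoints", "state"],
              "properties": {
                "box": {
                  "type": "array", "minItems": 4, "maxItems": 4,
                  "items": {"type": "number"},
                  "description": "[x0, y0, x1, y1], x1 > x0, y1 > y0"
                },
                "handedness": {"enum": ["left", "right"]},
                "keypoints": {
                  "type": "array", "minItems": 21, "maxItems": 21,
                  "items": {"type": "array", "minItems": 2, "maxItems": 2,
                            "items": {"type": "number"}},
                  "description": "joint order: wrist, thumb1-4, index1-4, middle1-4, ring1-4, pinky1-4 (base to tip)"
                },
                "state": {
                  "type": "array", "minItems": 21, "maxItems": 21,
                  "items": {"enum": ["visible", "occluded", "unannotated"]}
                },
                "confidence": {
                  "type": ["array", "null"],
                  "minItems": 21, "maxItems": 21,
                  "items": {"type": "number", "minimum": 0, "maximum": 1},
                  "description": "present on predictions only"
                },
                "track_id": {"type": ["integer", "null"], "minimum": 0,
                             "description": "unique within a frame; null when unset"}
              }
            }
          }
        }
      }
    }
  }
}
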