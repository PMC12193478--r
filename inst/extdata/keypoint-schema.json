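{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/gaitvar/keypoint-trial.schema.json",
  "title": "Keypoint trial",
  "description": "One walking trial of 17-keypoint 2-D pose detections. Keypoint order follows the common 17-point skeleton; 0-based indices 15 and 16 are the left and right foot. Coordinates are pixels (origin top-left, y downward); confidence lies in [0,1]. A keypoint entry may be null, standing for a missing detection (confidence 0 at the origin). A frame may alternatively be a flat array of 51 numbers (x1,y1,c1,...,x17,y17,c17).",
  "type": "object",
  "required": ["frames"],
  "properties": {
    "subject_id": { "type": "string" },
    "trial_id": { "type": "string" },
    "frames": {
      "type": "array",
      "items": {
        "oneOf": [
          {
            "type": "object",
            "required": ["keypoints"],
            "properties": {
              "keypoints": {
                "type": "array",
                "minItems": 17,
                "maxItems": 17,
                "items": {
                  "oneOf": [
                    { "type": "null" },
                    {
                      "type": "array",
                      "minItems": 2,
                      "maxItems": 3,
                      "items": { "type": "number" }
                    }
                  ]
                }
              }
            }
          },
          {
            "type": "array",
            "minItems": 51,
            "maxItems": 51,
            "items": { "type": "number" }
          }
        ]
      }
    }
  }
}
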