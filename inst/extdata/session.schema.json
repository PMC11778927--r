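{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "icdyn-session/1",
  "title": "icdyn session file",
  "description": "One unit's spike train plus the event/trial structure of the protocol it was recorded or simulated under. Times are seconds from session start; durations are milliseconds. Columns are stored column-wise (arrays of equal length). Unknown top-level keys are preserved on round-trip.",
  "type": "object",
  "required": ["schema", "session_id", "protocol", "design", "spikes"],
  "properties": {
    "schema": { "const": "icdyn-session/1" },
    "session_id": { "type": "string" },
    "protocol": { "enum": ["oddball", "reward"] },
    "design": {
      "type": "object",
      "required": ["type"],
      "properties": { "type": { "enum": ["oddball_design", "reward_protocol"] } }
    },
    "spikes": {
      "type": "object",
      "required": ["unit_id", "times"],
      "properties": {
        "unit_id": { "type": "string" },
        "times": {
          "type": "array",
          "items": { "type": "number", "minimum": 0 },
          "description": "sorted ascending; duplicates flagged, not rejected"
        }
      }
    },
    "blocks": {
      "type": "object",
      "description": "oddball only; equal-length column arrays",
      "properties": {
        "block_id": { "type": "array", "items": { "type": "integer" } },
        "deviant_level_n": { "type": "array", "items": { "type": "integer", "minimum": 0 } },
        "n_standards": { "type": "array", "items": { "type": "integer", "minimum": 1 } },
        "choice": { "type": "array", "items": { "enum": ["press", "no_press"] } },
        "press_time_s": { "type": "array", "items": { "type": ["number", "null"] } },
        "reward_time_s": { "type": "array", "items": { "type": ["number", "null"] } },
        "outcome": { "type": "array", "items": { "enum": ["hit", "miss", "correct_rejection", "false_alarm"] } }
      }
    },
    "events": {
      "type": "object",
      "description": "oddball only; one entry per stimulus",
      "properties": {
        "block_id": { "type": "array", "items": { "type": "integer" } },
        "onset_s": { "type": "array", "items": { "type": "number", "minimum": 0 } },
        "duration_ms": { "type": "array", "items": { "type": "number", "exclusiveMinimum": 0 } },
        "role": { "type": "array", "items": { "enum": ["standard", "deviant", "control_final"] } },
        "order_index": { "type": "array", "items": { "type": "integer", "minimum": 1 } }
      }
    },
    "trials": {
      "type": "object",
      "description": "reward protocol only",
      "properties": {
        "trial": { "type": "array", "items": { "type": "integer", "minimum": 1 } },
        "block": { "type": "array", "items": { "enum": ["early_no_reward", "reward", "late_no_reward"] } },
        "onset_s": { "type": "array", "items": { "type": "number", "minimum": 0 } },
        "duration_ms": { "type": "array", "items": { "type": "number", "exclusiveMinimum": 0 } },
        "reward_time_s": { "type": "array", "items": { "type": ["number", "null"] } }
      }
    },
    "meta": { "type": "object", "description": "free-form provenance, e.g. generator seed and ground-truth model parameters" }
  }
}
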