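{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "amtrack experiment configuration",
  "type": "object",
  "required": ["conditions"],
  "properties": {
    "conditions": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["carrier_hz", "mod_hz"],
        "properties": {
          "carrier_hz": {"type": "number", "exclusiveMinimum": 0},
          "mod_hz": {"type": "number", "exclusiveMinimum": 0}
        }
      }
    },
    "staircase": {
      "type": "object",
      "properties": {
        "start_value": {"type": "number", "default": 6},
        "step_sizes": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}, "default": [1, 0.5]},
        "change_points": {"type": "array", "items": {"type": "integer", "minimum": 0}, "default": [1]},
        "n_down": {"type": "integer", "minimum": 1, "default": 3},
        "schedule_mode": {"enum": ["reversal", "trial"], "default": "reversal"},
        "max_trials": {"type": "integer", "minimum": 1},
        "max_reversals": {"type": "integer", "minimum": 1},
        "min_value": {"type": "number"},
        "max_value": {"type": "number"}
      }
    },
    "observer": {
      "type": "object",
      "properties": {
        "midpoint_db": {"type": "number", "default": -9},
        "std_db": {"type": "number", "exclusiveMinimum": 0, "default": 2},
        "guess_rate": {"type": "number", "minimum": 0, "exclusiveMaximum": 1, "default": 0}
      }
    },
    "session": {
      "type": "object",
      "properties": {
        "n_participants": {"type": "integer", "minimum": 1, "default": 10},
        "reps_per_position": {"type": "integer", "minimum": 1, "default": 12},
        "repetitions": {"type": "integer", "minimum": 1, "default": 3},
        "stim_duration_s": {"type": "number", "exclusiveMinimum": 0, "default": 0.5},
        "onsets_s": {"type": "array", "items": {"type": "number", "minimum": 0}, "default": [0.5, 1.5, 2.5]},
        "trial_period_s": {"type": "number", "exclusiveMinimum": 0, "default": 4},
        "rate": {"type": "number", "exclusiveMinimum": 0, "default": 44100},
        "base_seed": {"type": "integer", "default": 1},
        "n_reversals": {"type": "integer", "minimum": 1, "default": 6}
      }
    },
    "calibration_file": {"type": "string"}
  }
}
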