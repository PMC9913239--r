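{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "thermodose analysis report",
  "type": "object",
  "required": ["fits", "model_comparison", "config"],
  "properties": {
    "fits": {
      "type": "object",
      "description": "keyed by recovery time (hours), then by cell line",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": {
          "type": "object",
          "required": ["arrhenius", "arrhenius_delayed", "two_state"],
          "properties": {
            "arrhenius": {
              "type": "object",
              "required": ["params", "r_squared"],
              "properties": {
                "params": {"$ref": "#/$defs/arrhenius_params"},
                "r_squared": {"type": "number"}
              }
            },
            "arrhenius_delayed": {
              "type": "object",
              "required": ["arrhenius", "delay", "r_squared"],
              "properties": {
                "arrhenius": {"$ref": "#/$defs/arrhenius_params"},
                "delay": {
                  "type": "object",
                  "required": ["slope_m", "intercept_b"],
                  "properties": {
                    "slope_m": {"type": "number", "minimum": 0},
                    "intercept_b": {"type": "number"}
                  }
                },
                "r_squared": {"type": "number"}
              }
            },
            "two_state": {
              "type": "object",
              "required": ["params", "r_squared"],
              "properties": {
                "params": {
                  "type": "object",
                  "required": ["alpha", "beta", "gamma"],
                  "properties": {
                    "alpha": {"type": "number"},
                    "beta": {"type": "number"},
                    "gamma": {"type": "number"}
                  }
                },
                "r_squared": {"type": "number"}
              }
            },
            "r_cem": {"type": ["number", "null"]},
            "decay_rates": {
              "type": "array",
              "items": {
                "type": "object",
                "required": ["temperature", "rate_k", "shoulder_td"],
                "properties": {
                  "temperature": {"type": "number", "exclusiveMinimum": 0},
                  "rate_k": {"type": "number", "exclusiveMinimum": 0},
                  "shoulder_td": {"type": "number", "minimum": 0},
                  "r_squared": {"type": "number"},
                  "n_points": {"type": "integer"}
                }
              }
            }
          }
        }
      }
    },
    "model_comparison": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["recovery_h", "model", "rmse_pct"],
        "properties": {
          "recovery_h": {"type": "number"},
          "model": {"enum": ["arrhenius", "arrhenius_delayed", "two_state"]},
          "rmse_pct": {"type": "number", "minimum": 0}
        }
      }
    },
    "validation": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "properties": {
          "profile": {"type": "string"},
          "model": {"type": "string"},
          "predicted_pct": {"type": "number"},
          "reference_pct": {"type": "number"},
          "abs_error_pct": {"type": "number", "minimum": 0}
        }
      }
    },
    "config": {
      "type": "object",
      "required": ["gas_constant", "recovery_h", "clip_floor", "logit_eps",
                   "r_above", "r_below", "break_temperature"],
      "properties": {
        "gas_constant": {"type": "number", "exclusiveMinimum": 0},
        "recovery_h": {"type": "number"},
        "clip_floor": {"type": "number"},
        "clip_ceiling": {"type": "number"},
        "logit_eps": {"type": "number"},
        "r_above": {"type": "number"},
        "r_below": {"type": "number"},
        "break_temperature": {"type": "number"},
        "seed": {"type": ["integer", "null"]}
      }
    }
  },
  "$defs": {
    "arrhenius_params": {
      "type": "object",
      "required": ["ln_frequency_factor", "activation_energy", "gas_constant"],
      "properties": {
        "ln_frequency_factor": {"type": "number"},
        "activation_energy": {"type": "number", "exclusiveMinimum": 0},
        "gas_constant": {"type": "number", "exclusiveMinimum": 0}
      }
    }
  }
}
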