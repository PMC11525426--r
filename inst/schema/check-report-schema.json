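{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "bfcheck check report",
  "type": "object",
  "required": ["pair", "m", "seed", "theorem1", "universal_bound",
               "weight_of_evidence", "undefined_count", "failed_count",
               "recode_policy"],
  "properties": {
    "pair": {
      "type": "object",
      "required": ["specific", "general"],
      "properties": {
        "specific": {"type": "string"},
        "general": {"type": "string"}
      }
    },
    "m": {"type": "integer", "minimum": 2},
    "seed": {"type": "integer"},
    "observed_bf": {"type": ["number", "null"]},
    "theorem1": {
      "type": "object",
      "required": ["mean", "mc_se", "m_used", "verdict",
                   "tolerance_multiplier", "heavy_tail_caution"],
      "properties": {
        "mean": {"type": "number"},
        "mc_se": {"type": "number", "minimum": 0},
        "m_used": {"type": "integer"},
        "verdict": {"enum": ["pass", "fail"]},
        "tolerance_multiplier": {"type": "number"},
        "heavy_tail_caution": {"type": "boolean"}
      }
    },
    "theorem2": {
      "type": ["object", "null"],
      "properties": {
        "order_low": {"type": "integer"},
        "moment_specific_true": {"type": "number"},
        "moment_general_true": {"type": "number"},
        "relative_difference": {"type": "number"},
        "verdict": {"enum": ["pass", "fail"]}
      }
    },
    "universal_bound": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["alpha", "threshold", "empirical_fraction",
                     "bound_satisfied"]
      }
    },
    "weight_of_evidence": {
      "type": "object",
      "required": ["mean_log_bf", "sd_log_bf", "skewness_bf"]
    },
    "undefined_count": {"type": "integer"},
    "failed_count": {"type": "integer"},
    "recode_policy": {"type": "string"}
  }
}
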