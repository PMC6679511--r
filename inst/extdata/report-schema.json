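{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "behavior_report",
  "description": "Caregiver-facing synthesis report produced by run_pipeline(); version 1.0. Contains derived summaries only, never raw event payloads.",
  "type": "object",
  "required": ["schema_version", "subject", "period", "parameters"],
  "properties": {
    "schema_version": { "type": "string" },
    "subject": { "type": "string" },
    "period": {
      "type": "object",
      "required": ["start", "end"],
      "properties": {
        "start": { "type": "string", "format": "date" },
        "end": { "type": "string", "format": "date" }
      }
    },
    "parameters": {
      "type": "object",
      "required": ["timezone", "bin_width", "tmin", "window", "abrupt",
                   "intermediate", "alpha", "level", "n_sam", "k_max",
                   "visit_gap", "gap_merge", "min_rest_duration",
                   "confirm_window", "night_window", "period_hours", "seed"],
      "properties": {
        "timezone": { "type": "string" },
        "bin_width": { "type": "number" },
        "tmin": { "type": "number" },
        "window": { "type": "integer" },
        "abrupt": { "type": "integer" },
        "intermediate": { "type": "integer" },
        "alpha": { "type": "number" },
        "level": { "type": "number" },
        "n_sam": { "type": "integer" },
        "k_max": { "type": "integer" },
        "epsilon": { "type": ["number", "null"] },
        "visit_gap": { "type": "number" },
        "gap_merge": { "type": "number" },
        "min_rest_duration": { "type": "number" },
        "confirm_window": { "type": "number" },
        "night_window": { "type": "array", "items": { "type": "string" } },
        "period_hours": { "type": "number" },
        "seed": { "type": "integer" }
      }
    },
    "quality": {
      "type": ["object", "null"],
      "properties": {
        "n_total_days": { "type": "integer" },
        "n_ideal_days": { "type": "integer" },
        "n_severe_days": { "type": "integer" },
        "pct_ideal": { "type": "number" },
        "pct_severe": { "type": "number" }
      }
    },
    "trends": {
      "type": ["object", "null"],
      "properties": {
        "n_days": { "type": "integer" },
        "n_analysis_dates": { "type": "integer" },
        "alert_dates": { "type": "array", "items": { "type": "string" } },
        "unexplained_dates": { "type": "array", "items": { "type": "string" } },
        "last_day": { "type": "object" }
      }
    },
    "profiles": {
      "type": ["object", "null"],
      "properties": {
        "n_days": { "type": "integer" },
        "n_rest_intervals": { "type": "integer" },
        "pct_confirmed_ends": { "type": ["number", "null"] },
        "profile": { "type": "array" },
        "n_clusters": { "type": ["integer", "null"] },
        "silhouette": { "type": ["number", "null"] },
        "cluster_sizes": { "type": ["object", "null"] },
        "novelty_threshold": { "type": ["number", "null"] },
        "deviant_dates": { "type": "array", "items": { "type": "string" } },
        "deviant_ns": { "type": "array", "items": { "type": "number" } }
      }
    }
  }
}
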