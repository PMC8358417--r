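{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "trial-record.schema.json",
  "title": "TrialRecord",
  "description": "One randomised-trial comparison (or prespecified subgroup row) in recurrent ovarian cancer, as consumed by the MCBS grading pipeline. Absent fields are omitted or null; an absent value is distinct from zero.",
  "type": "object",
  "required": ["trial_id", "setting", "design", "n", "experimental_label",
               "comparator_label", "primary_endpoint"],
  "properties": {
    "trial_id": {"type": "string", "minLength": 1},
    "study_name": {"type": ["string", "null"]},
    "setting": {"enum": ["platinum_sensitive", "maintenance", "platinum_resistant"]},
    "design": {"enum": ["phase3_rct", "phase2_rct", "other"]},
    "n": {"type": "integer", "minimum": 1},
    "experimental_label": {"type": "string"},
    "comparator_label": {"type": "string"},
    "primary_endpoint": {"enum": ["OS", "PFS", "ORR", "QOL_TOX", "NONINFERIORITY"]},
    "endpoints": {
      "type": "array",
      "items": {"$ref": "#/$defs/endpoint_summary"}
    },
    "evidence": {"$ref": "#/$defs/evidence_flags"},
    "subgroup_of": {"type": ["string", "null"]},
    "subgroup_prespecified": {"type": "boolean"},
    "comparator_adequate": {"type": "boolean"},
    "terminated_early": {"type": "boolean"},
    "superseded": {"type": "boolean"}
  },
  "$defs": {
    "endpoint_summary": {
      "type": "object",
      "required": ["endpoint", "significant"],
      "properties": {
        "endpoint": {"enum": ["OS", "PFS", "ORR", "QOL_TOX"]},
        "control_median": {"type": ["number", "null"], "minimum": 0},
        "gain": {"type": ["number", "null"]},
        "hazard_ratio": {"type": ["number", "null"], "exclusiveMinimum": 0},
        "hr_lower": {"type": ["number", "null"], "exclusiveMinimum": 0},
        "hr_upper": {"type": ["number", "null"], "exclusiveMinimum": 0},
        "orr_pct": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
        "significant": {"enum": ["confirmed", "not_significant",
                                 "exploratory_or_unreported"]}
      }
    },
    "evidence_flags": {
      "type": "object",
      "properties": {
        "qol_reported": {"type": "boolean"},
        "qol_global_improved": {"type": "boolean"},
        "qol_subscale_improved": {"type": "boolean"},
        "toxicity_reduced": {"type": "boolean"},
        "toxicity_increased": {"type": "boolean"},
        "early_discontinuation_reduced": {"type": "boolean"}
      }
    }
  }
}
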