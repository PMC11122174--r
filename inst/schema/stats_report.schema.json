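{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "orbitometry-stats-report-v1",
  "title": "orbitometry statistics report",
  "type": "object",
  "required": ["n_subjects", "normality", "group_tests", "model", "r2",
               "gender_diff_pct", "va_ratio"],
  "properties": {
    "n_subjects": {"type": "integer", "minimum": 0},
    "normality": {"type": "array"},
    "group_tests": {"type": "object"},
    "model": {"type": "object"},
    "r2": {"type": "array"},
    "gender_diff_pct": {"type": "number"},
    "va_ratio": {"type": "object"},
    "flagged_ids": {"type": "array"},
    "failures": {"type": "array"}
  }
}
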