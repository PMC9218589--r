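{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/fairVCF/validation-report.schema.json",
  "title": "fairVCF validation report",
  "type": "object",
  "required": ["file_path", "profile_version", "strict", "passed",
               "counts", "issues"],
  "additionalProperties": false,
  "properties": {
    "file_path": {"type": "string"},
    "profile_version": {"type": "string"},
    "strict": {"type": "boolean"},
    "passed": {"type": "boolean"},
    "counts": {
      "type": "object",
      "required": ["errors", "warnings", "infos"],
      "additionalProperties": false,
      "properties": {
        "errors": {"type": "integer", "minimum": 0},
        "warnings": {"type": "integer", "minimum": 0},
        "infos": {"type": "integer", "minimum": 0}
      }
    },
    "issues": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rule_id", "severity", "message"],
        "additionalProperties": false,
        "properties": {
          "rule_id": {"type": "string", "pattern": "^FVCF-[A-Z]+-[0-9]{3}$"},
          "severity": {"enum": ["error", "warning", "info"]},
          "line_number": {"type": ["integer", "null"]},
          "message": {"type": "string", "minLength": 1},
          "observed": {"type": ["string", "null"]}
        }
      }
    }
  }
}
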