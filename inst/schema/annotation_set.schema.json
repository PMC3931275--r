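{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "variotools annotation set",
  "type": "object",
  "required": ["ontology_version", "variant", "levels_affected",
               "reference_states", "annotations"],
  "properties": {
    "ontology_version": {"type": "string"},
    "variant": {
      "type": "object",
      "required": ["hgvs", "reference_id"],
      "properties": {
        "hgvs": {"type": "string"},
        "reference_id": {"type": "string"}
      }
    },
    "levels_affected": {
      "type": "array",
      "items": {"enum": ["DNA", "RNA", "protein"]}
    },
    "reference_states": {
      "type": "object",
      "additionalProperties": {"type": "string"}
    },
    "annotations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["level", "path", "ambiguous_path", "extra_terms",
                     "attributes", "evidence", "references"],
        "properties": {
          "level": {"enum": ["DNA", "RNA", "protein"]},
          "path": {
            "type": "array", "minItems": 1,
            "items": {"type": "string",
                      "pattern": "^(VariO:[0-9]{4}|ECO:[0-9]{7})$"}
          },
          "ambiguous_path": {"type": "boolean"},
          "extra_terms": {
            "type": "array",
            "items": {"type": "string", "pattern": "^VariO:[0-9]{4}$"}
          },
          "attributes": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["attribute_id", "modified_term_id"],
              "properties": {
                "attribute_id": {"type": "string",
                                 "pattern": "^VariO:[0-9]{4}$"},
                "modified_term_id": {"type": "string",
                                     "pattern": "^VariO:[0-9]{4}$"},
                "full_path": {
                  "type": ["array", "null"],
                  "items": {"type": "string",
                            "pattern": "^VariO:[0-9]{4}$"}
                }
              }
            }
          },
          "evidence": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["eco_id", "eco_name"],
              "properties": {
                "eco_id": {"type": "string", "pattern": "^ECO:[0-9]{7}$"},
                "eco_name": {"type": "string"},
                "linked_term_id": {"type": "string"}
              }
            }
          },
          "references": {"type": "array", "items": {"type": "string"}}
        }
      }
    }
  }
}
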