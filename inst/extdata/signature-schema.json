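{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "sigsurv signature definition",
  "type": "object",
  "required": ["name", "archetype", "genes"],
  "additionalProperties": false,
  "properties": {
    "name": {"type": "string", "minLength": 1},
    "archetype": {
      "enum": ["centroid_subtype", "centroid_risk", "weighted_sum",
               "difference_of_means", "grouped_threshold"]
    },
    "genes": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["gene_id"],
        "properties": {
          "gene_id": {"type": "string"},
          "weight": {"type": "number"},
          "group": {"type": "string"},
          "stratum": {"type": "string"},
          "reference": {"type": "boolean"}
        }
      }
    },
    "centroids": {
      "type": "object",
      "required": ["classes", "gene_ids", "values"],
      "properties": {
        "classes": {"type": "array", "items": {"type": "string"}},
        "gene_ids": {"type": "array", "items": {"type": "string"}},
        "values": {
          "description": "row-major genes x classes",
          "type": "array",
          "items": {"type": "array", "items": {"type": "number"}}
        }
      }
    },
    "ror_coefficients": {
      "type": "object",
      "additionalProperties": {"type": "number"}
    },
    "reference_class": {"type": "string"},
    "group_weights": {
      "type": "object",
      "additionalProperties": {"type": "number"}
    },
    "clip": {
      "description": "per-group [low, high] clipping bounds",
      "type": "object",
      "additionalProperties": {
        "type": "array", "minItems": 2, "maxItems": 2,
        "items": {"type": "number"}
      }
    },
    "intercept": {"type": "number"},
    "risk_direction": {"enum": [1, -1]},
    "classify_method": {"enum": ["pearson", "spearman"]},
    "score_method": {"enum": ["pearson", "spearman"]},
    "calibration": {
      "type": "object",
      "required": ["labels"],
      "properties": {
        "labels": {"type": "array", "items": {"type": "string"}},
        "proportions": {"type": "array", "items": {"type": "number"}},
        "by_stratum": {
          "type": "object",
          "additionalProperties": {
            "type": "array", "items": {"type": "number"}
          }
        }
      }
    }
  }
}
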