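{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "isodeconv gene fit report",
  "type": "object",
  "required": ["gene_id", "k", "k_estimated", "loss", "n_outliers", "improvements", "threshold", "timings"],
  "properties": {
    "gene_id": {"type": "string"},
    "k": {"type": "integer"},
    "k_estimated": {"type": "boolean"},
    "loss": {"type": "number"},
    "n_outliers": {"type": "integer"},
    "seed": {"type": "integer"},
    "improvements": {"type": "string"},
    "threshold": {"type": "number"},
    "timings": {"type": "object"}
  }
}
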