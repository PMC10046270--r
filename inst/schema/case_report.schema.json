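{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "melwgs per-case report",
  "type": "object",
  "required": ["case_id", "burden", "exposures", "fit", "etiology", "msi_status"],
  "properties": {
    "case_id": {"type": "string"},
    "burden": {
      "type": "object",
      "required": ["total_mutations", "pathogenic_per_exome", "wgs_tmb_per_mb", "panel_tmb_equiv", "tmb_high"],
      "properties": {
        "total_mutations": {"type": "integer", "minimum": 0},
        "pathogenic_per_exome": {"type": "integer", "minimum": 0},
        "wgs_tmb_per_mb": {"type": "number", "minimum": 0},
        "panel_tmb_equiv": {"type": "number", "minimum": 0},
        "tmb_high": {"type": "boolean"}
      }
    },
    "exposures": {"type": "object"},
    "fit": {
      "type": "object",
      "required": ["log_likelihood", "n_iterations", "converged"],
      "properties": {
        "log_likelihood": {"type": "number"},
        "n_iterations": {"type": "integer"},
        "converged": {"type": "boolean"}
      }
    },
    "etiology": {
      "type": "object",
      "required": ["uv_share", "uv_band", "apobec_flag", "hrd_band"],
      "properties": {
        "uv_share": {"type": "number", "minimum": 0, "maximum": 1},
        "uv_band": {"enum": ["predominant", "minor"]},
        "apobec_flag": {"type": "boolean"},
        "hrd_band": {"enum": ["none", "minor", "present"]}
      }
    },
    "cnv": {
      "type": ["object", "null"],
      "required": ["n_total", "n_amplification", "n_trisomy_gain", "n_homozygous_loss", "n_loh", "loh_percent", "hrd_loh_score", "hrd_high"]
    },
    "msi_status": {"enum": ["MSS", "MSI", "unknown"]}
  }
}
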