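{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "hrvretest reliability report",
  "type": "object",
  "required": ["delta_summary", "concordance", "bland_altman", "metadata"],
  "properties": {
    "delta_summary": {
      "description": "SEXIT summary of the between-session difference model, one entry per HRV index and condition",
      "required_columns": ["index_name", "condition", "n", "n_outliers_removed",
        "median", "ci_low", "ci_high", "pd", "rope_low", "rope_high",
        "rope_pct_inside", "rope_label", "rhat", "ess", "bf10", "bf_label",
        "pass"]
    },
    "concordance": {
      "description": "Bayesian Lin's CCC per HRV index and condition",
      "required_columns": ["index_name", "condition", "ccc", "interpretation",
        "ci_low", "ci_high"]
    },
    "bland_altman": {
      "description": "Bias and 95% limits of agreement per HRV index and condition",
      "required_columns": ["index_name", "condition", "bias", "loa_low",
        "loa_high"]
    },
    "hrmax": {
      "description": "Optional per-session relative intensity summary",
      "required_columns": ["session", "n", "median", "q2.5", "q97.5"]
    },
    "metadata": {
      "description": "Seed and analysis settings sufficient to re-run the report",
      "required_columns": ["seed", "chains", "iterations", "warmup",
        "rope_multiplier", "prior_multiplier", "package_version"]
    }
  }
}
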