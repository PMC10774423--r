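{
  "title": "bir2dyn variant report",
  "type": "object",
  "required": ["variant", "mechanism", "rmsd_core_median", "rmsd_core_q90",
               "rmsf_174_182", "rmsf_192_198", "rmsf_205_215",
               "hbond_166_185_pct", "beta_distance", "rca", "seeds",
               "config_hash"],
  "properties": {
    "variant": {"type": "string"},
    "mechanism": {"type": "string"},
    "rmsd_core_median": {"type": "number", "minimum": 0},
    "rmsd_core_q90": {"type": "number", "minimum": 0},
    "rmsf_174_182": {"type": "number", "minimum": 0},
    "rmsf_192_198": {"type": "number", "minimum": 0},
    "rmsf_205_215": {"type": "number", "minimum": 0},
    "hbond_166_185_pct": {"type": "number", "minimum": 0, "maximum": 100},
    "beta_distance": {"type": "number", "minimum": 0},
    "rca": {"type": "number", "minimum": -0.1, "maximum": 1.5},
    "bound_fraction_true": {"type": "number", "minimum": 0, "maximum": 1},
    "seeds": {"type": "string"},
    "config_hash": {"type": "string"}
  }
}
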