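{
  "required": ["package", "seed", "stages"],
  "stage_status": ["ok", "failed", "skipped"],
  "optional_sections": ["transfer", "gpoe", "envgwas", "clump",
                        "enrichment", "bench"]
}
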