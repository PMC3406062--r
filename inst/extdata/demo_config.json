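{
  "seed": 42,
  "output_dir": "mostwanted_demo",
  "simulate": {
    "preset": "standard",
    "n_sources": 12,
    "samples_per_site": 6,
    "reads_per_sample": 60
  }
}
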