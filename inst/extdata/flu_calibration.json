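{
  "analyte": "fluconazole",
  "detection": "UV 210 nm",
  "slope": 30676,
  "intercept": 2843.9,
  "range_low": 0.5,
  "range_high": 10,
  "lod": 0.007,
  "loq": 0.021
}
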