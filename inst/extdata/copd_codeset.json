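{
  "name": "COPD-default",
  "icd9": ["491", "491.1", "491.2", "491.21", "491.22", "491.8", "491.9", "492", "492.8", "493.92", "496"],
  "icd10": ["J41.0", "J41.1", "J41.8", "J42", "J43.1", "J43.2", "J43.8", "J43.9", "J44.0", "J44.1", "J44.9"]
}
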