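{
  "transporter": "pgp",
  "vip_threshold": 0.75,
  "members": {
    "metabolite": ["pyridoxine", "glutamine", "arginine", "creatinine",
                   "leucine", "methylcysteine", "phenylalanine", "methionine",
                   "threonine", "nicotinamide", "pantothenate"],
    "direction": ["up", "up", "up", "up", "up", "up", "up", "up", "up", "up", "up"]
  }
}
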