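{
  "transporter": "mrp2",
  "vip_threshold": 0.75,
  "members": {
    "metabolite": ["arginine", "S-adenosyl-L-homocysteine", "threonine",
                   "serine", "S-adenosyl-L-methionine", "pantothenate",
                   "alanine", "carnitine", "acetylcarnitine"],
    "direction": ["up", "up", "up", "up", "up", "up", "up", "up", "down"]
  }
}
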