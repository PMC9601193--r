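{
  "transporter": "bcrp",
  "vip_threshold": 0.75,
  "members": {
    "metabolite": ["glutamate", "hypoxanthine", "xanthine", "pantothenate"],
    "direction": ["down", "down", "down", "up"]
  }
}
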