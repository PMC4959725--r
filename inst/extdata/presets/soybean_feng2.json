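{
  "name": "soybean_feng2",
  "description": "High-oil soybean Feng2: smaller seeds (0.12-0.3 g), OCR N(20.4, 1.0) (weight sd is synthetic)",
  "classes": {
    "unknown": {"ocr_mean": 20.4, "ocr_sd": 1.0, "weight_mean": 0.21, "weight_sd": 0.03}
  },
  "wcr_mean": 10.0,
  "wcr_sd": 1.0
}
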