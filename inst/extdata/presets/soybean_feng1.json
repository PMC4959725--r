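{
  "name": "soybean_feng1",
  "description": "High-oil soybean Feng1: larger seeds (0.35-0.6 g), OCR N(17.5, 2.0) (weight sd is synthetic)",
  "classes": {
    "unknown": {"ocr_mean": 17.5, "ocr_sd": 2.0, "weight_mean": 0.475, "weight_sd": 0.04}
  },
  "wcr_mean": 10.0,
  "wcr_sd": 1.0
}
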