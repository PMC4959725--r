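{
  "name": "maize_zd958_induction",
  "description": "ZD958 x CHOI3 with realistic induction-rate haploid fraction (321/3742)",
  "classes": {
    "haploid": {"ocr_mean": 3.6, "ocr_sd": 0.47, "weight_mean": 0.40, "weight_sd": 0.049},
    "diploid": {"ocr_mean": 5.5, "ocr_sd": 0.52, "weight_mean": 0.43, "weight_sd": 0.035}
  },
  "haploid_fraction": 0.086,
  "wcr_mean": 10.0,
  "wcr_sd": 1.0
}
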