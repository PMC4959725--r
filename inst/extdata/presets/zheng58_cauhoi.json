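{
  "name": "zheng58_cauhoi",
  "description": "Zheng58 x CAUHOI cross; diploid OCR centred on the 6.7% stability-test kernel, diploid OCR more than twice haploid for this line (class sds and haploid parameters are synthetic)",
  "classes": {
    "haploid": {"ocr_mean": 3.2, "ocr_sd": 0.4, "weight_mean": 0.40, "weight_sd": 0.045},
    "diploid": {"ocr_mean": 6.7, "ocr_sd": 0.5, "weight_mean": 0.42, "weight_sd": 0.04}
  },
  "haploid_fraction": 0.5,
  "wcr_mean": 10.0,
  "wcr_sd": 1.0
}
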