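{
  "left": ["C", "AC", "C", "TAG", "C", "C", "TC"],
  "right": ["GA", "G", "ATC", "G", "TG", "G"],
  "gap_min": 0,
  "gap_max": 50
}
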