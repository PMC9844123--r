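gates:
  empty_gate:
    area_ratio_max: 1.08
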