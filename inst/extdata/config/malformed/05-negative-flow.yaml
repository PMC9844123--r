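flow:
  sample: "-0.01 ul/s"
  sheath: "0.07 ul/s"
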