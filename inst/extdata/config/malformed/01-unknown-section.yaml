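geometry:
  deformation_channel: "30 um"
acoustics:
  power: "1.9 W"
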