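geometry:
  deformation_channel: "30 um"
  sorting_width: "50 um"
  sorting_length: "130 um"
  volume: "0.4 nl"
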