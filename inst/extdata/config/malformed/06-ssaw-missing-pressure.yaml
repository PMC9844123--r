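field:
  mode: SSAW
  frequency: "55 MHz"
  wavelength: "70 um"
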