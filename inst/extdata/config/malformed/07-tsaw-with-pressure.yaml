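field:
  mode: TSAW
  frequency: "135 MHz"
  energy_density: "100 J/m3"
  pressure_amplitude: "100 kPa"
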