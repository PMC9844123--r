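# Reference run configuration: bead-mixture sorting in a 30 um chip.
# Every physical quantity is a string with an explicit unit; values are
# converted to SI on load and the schema is closed (unknown keys rejected).
geometry:
  deformation_channel: "30 um"
  sorting_width: "50 um"
  sorting_length: "130 um"
  bifurcation_offset: "5 um"
  volume: "0.2 nl"
flow:
  sample: "0.01 ul/s"
  sheath: "0.07 ul/s"
fluid:
  density: "998 kg/m3"
  compressibility: "4.58e-10 1/Pa"
  sound_speed: "1487 m/s"
  viscosity: "10 mPa s"
particle:
  diameter: "12.6 um"
  density: "1050 kg/m3"
  compressibility: "4.0e-10 1/Pa"
  Y_T: 1.0
field:
  mode: TSAW
  frequency: "135 MHz"
  energy_density: "100 J/m3"
  pulse_duration: "1 ms"
idt:
  finger_periodicity: "28 um"
  substrate_sound_speed: "3978 m/s"
  aperture: "100 um"
  focal_length: "170 um"
  design: focused
gates:
  bead_small:
    area_range: [115, 135]
    area_ratio_max: 1.05
simulation:
  duration: "60 s"
  concentration: "24e6 cells/ml"
  mixture:
    bead_small: 0.4
    bead_large: 0.6
  seed: 1
  coincidence_policy: abort
  delay: "1 ms"
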