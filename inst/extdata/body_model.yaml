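# Reduced nine-segment body model with de Leva-style mass proportions
# (fractions are renormalised on load; any positive scale works).
total_mass: 80.0
gravity: 9.81
segments:
  pelvis: 11.17
  trunk: 32.29
  head_arms: 16.82
  thigh_L: 14.16
  thigh_R: 14.16
  shank_L: 4.33
  shank_R: 4.33
  foot_L: 1.37
  foot_R: 1.37
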