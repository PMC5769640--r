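# Hovering flat-plate validation case (closed mineral-oil tank).
fluid:
  standard: oil
profile:
  type: plate
  chord: 23.85
  thickness_ratio: 0.1
kinematics:
  mode: hover-validation
case:
  boundary_mode: closed-tank-validation
  coef_velocity: kinematic
  domain_c: [10, 10]
  preset: coarse
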