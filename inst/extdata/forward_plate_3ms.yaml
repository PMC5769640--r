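# Flat plate under bee forward-flight kinematics at 3 m/s.
fluid:
  standard: air
profile:
  type: plate
  chord: 4
  thickness_ratio: 0.0125
kinematics:
  V_inf_lookup: 3
case:
  boundary_mode: open-forward-flight
  coef_velocity: kinematic
  V_inf: 3
  domain_c: [22, 11]
  preset: coarse
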