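# Illustrative template model: R-enantiomer of omeprazole (see
# esomeprazole.yaml). CYP2C19-dominant clearance; gut CYP2C19 expression may
# be lowered via scale_gut_expression() to emulate the higher-than-expected
# oral bioavailability of this enantiomer.
schema: pbpkddi-drug/1
name: r-omeprazole
molecular_weight: 345.42
fu: 0.05
blood_plasma_ratio: 1.0
kp_map:
  default: 0.25
pathways:
- enzyme: CYP2C19
  kinetics: linear
  cl_int: 15.2 L/min
- enzyme: CYP3A4
  kinetics: linear
  cl_int: 0.135 L/min
inhibitions:
- target_enzyme: CYP2C19
  mechanism: competitive
  ki: 5.3 uM
  basis: in_vitro
- target_enzyme: CYP2C19
  mechanism: tdi
  k_i_tdi: 1.6 uM
  k_inact: 0.05 1/min
  basis: in_vitro
  note: k_inact illustrative (autoinhibition)
absorption:
  ka: 0.03 1/min
  f_abs: 1.0
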