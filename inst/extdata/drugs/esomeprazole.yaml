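# Illustrative template model: S-enantiomer of omeprazole. Racemic
# omeprazole is modeled as esomeprazole + r-omeprazole co-dosed at half the
# racemate dose each, with mutual CYP2C19 inhibition. Competitive Ki and the
# TDI binding constant are library values; k_inact and all PK parameters are
# illustrative placeholders.
schema: pbpkddi-drug/1
name: esomeprazole
molecular_weight: 345.42
fu: 0.05
blood_plasma_ratio: 1.0
kp_map:
  default: 0.25
pathways:
- enzyme: CYP2C19
  kinetics: linear
  cl_int: 11.9 L/min
- enzyme: CYP3A4
  kinetics: linear
  cl_int: 0.41 L/min
inhibitions:
- target_enzyme: CYP2C19
  mechanism: competitive
  ki: 3.1 uM
  basis: in_vitro
- target_enzyme: CYP2C19
  mechanism: tdi
  k_i_tdi: 0.3 uM
  k_inact: 0.05 1/min
  basis: in_vitro
  note: k_inact illustrative (autoinhibition)
absorption:
  ka: 0.03 1/min
  f_abs: 1.0
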