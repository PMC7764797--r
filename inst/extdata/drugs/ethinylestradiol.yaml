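# Illustrative template model: moderate CYP1A2 perpetrator with five parallel
# metabolic pathways (CYP3A4, CYP1A2, CYP2C9, CYP2C19 linear; UGT1A1
# saturable). Carries both a competitive CYP1A2 inhibition (optimized library
# value; literature 10.6 uM) and a CYP1A2 TDI whose two candidate k_inact
# values (100 and 200 1/min) are compared via compare_mechanisms(); the file
# default is 100 1/min. The TDI binding constant and PK parameters are
# illustrative placeholders.
schema: pbpkddi-drug/1
name: ethinylestradiol
molecular_weight: 296.4
fu: 0.03
blood_plasma_ratio: 1.0
kp_map:
  default: 5
pathways:
- enzyme: CYP3A4
  kinetics: linear
  cl_int: 0.08 L/min
- enzyme: CYP1A2
  kinetics: linear
  cl_int: 0.05 L/min
- enzyme: CYP2C9
  kinetics: linear
  cl_int: 0.01 L/min
- enzyme: CYP2C19
  kinetics: linear
  cl_int: 0.02 L/min
- enzyme: UGT1A1
  kinetics: saturable
  vmax: 0.002 1/min
  km: 0.02 uM
inhibitions:
- target_enzyme: CYP1A2
  mechanism: competitive
  ki: 0.48 uM
  basis: optimized
  note: literature value 10.6 uM
- target_enzyme: CYP1A2
  mechanism: tdi
  k_i_tdi: 0.48 uM
  k_inact: 100 1/min
  basis: optimized
  note: k_inact candidates 100 and 200 1/min; KI illustrative
absorption:
  ka: 0.04 1/min
  f_abs: 1.0
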