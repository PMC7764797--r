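# Illustrative template model: CYP2C19 victim and moderate perpetrator with
# saturable CYP2C19 metabolism, an unspecified (FMO-like) metabolic route,
# and CYP2C19 time-dependent autoinhibition. Competitive Ki and TDI binding
# constant are library values; k_inact and PK parameters are illustrative.
schema: pbpkddi-drug/1
name: moclobemide
molecular_weight: 268.74
fu: 0.5
blood_plasma_ratio: 1.0
kp_map:
  default: 1.2
pathways:
- enzyme: CYP2C19
  kinetics: saturable
  vmax: 28.6 1/min
  km: 20 uM
- enzyme: UNSPECIFIC
  kinetics: unspecific_hepatic
  cl_apparent: 0.4 L/min
inhibitions:
- target_enzyme: CYP2C19
  mechanism: competitive
  ki: 203.83 uM
  basis: in_vitro
- target_enzyme: CYP2C19
  mechanism: tdi
  k_i_tdi: 94.85 uM
  k_inact: 0.05 1/min
  basis: in_vitro
  note: k_inact illustrative (autoinhibition)
absorption:
  ka: 0.03 1/min
  f_abs: 1.0
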