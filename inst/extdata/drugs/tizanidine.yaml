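# Illustrative template model: high-extraction CYP1A2 victim with linear
# CYP1A2 metabolism as the only clearance pathway. PK parameters are
# illustrative placeholders.
schema: pbpkddi-drug/1
name: tizanidine
molecular_weight: 253.71
fu: 0.7
blood_plasma_ratio: 1.0
kp_map:
  default: 2.5
pathways:
- enzyme: CYP1A2
  kinetics: linear
  cl_int: 11.5 L/min
inhibitions: []
absorption:
  ka: 0.025 1/min
  f_abs: 1.0
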