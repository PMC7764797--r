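# Illustrative template model: CYP1A2 probe victim (dietary compound; the
# dietary tag enables the background-intake non-compliance generator). PK
# parameters are illustrative placeholders.
schema: pbpkddi-drug/1
name: caffeine
molecular_weight: 194.19
fu: 0.65
blood_plasma_ratio: 1.0
kp_map:
  default: 0.7
pathways:
- enzyme: CYP1A2
  kinetics: linear
  cl_int: 0.06 L/min
- enzyme: UNSPECIFIC
  kinetics: unspecific_hepatic
  cl_apparent: 0.008 L/min
inhibitions: []
absorption:
  ka: 0.05 1/min
  f_abs: 1.0
tags:
- dietary
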