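# Illustrative template model: CYP2C19 probe victim. The unspecific hepatic
# clearance is scaled from an in vivo apparent clearance and is insensitive
# to inhibitors; the CYP2C19 pathway carries the DDI. PK parameters are
# illustrative placeholders.
schema: pbpkddi-drug/1
name: s-mephenytoin
molecular_weight: 218.25
fu: 0.55
blood_plasma_ratio: 1.0
kp_map:
  default: 0.8
pathways:
- enzyme: CYP2C19
  kinetics: linear
  cl_int: 2.87 L/min
- enzyme: UNSPECIFIC
  kinetics: unspecific_hepatic
  cl_apparent: 0.45 L/min
inhibitions: []
absorption:
  ka: 0.02 1/min
  f_abs: 1.0
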