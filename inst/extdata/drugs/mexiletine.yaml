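# Illustrative template model: CYP1A2 victim and moderate CYP1A2 perpetrator
# with three parallel pathways (CYP2D6, CYP1A2, unspecific clearance). The
# competitive Ki is a library value; PK parameters are illustrative.
schema: pbpkddi-drug/1
name: mexiletine
molecular_weight: 179.26
fu: 0.3
blood_plasma_ratio: 1.0
kp_map:
  default: 7
pathways:
- enzyme: CYP2D6
  kinetics: linear
  cl_int: 2.28 L/min
- enzyme: CYP1A2
  kinetics: linear
  cl_int: 0.242 L/min
- enzyme: UNSPECIFIC
  kinetics: unspecific_hepatic
  cl_apparent: 0.13 L/min
inhibitions:
- target_enzyme: CYP1A2
  mechanism: competitive
  ki: 0.28 uM
  basis: in_vitro
absorption:
  ka: 0.03 1/min
  f_abs: 1.0
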