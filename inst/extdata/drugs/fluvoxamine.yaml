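# Illustrative template model: strong CYP2C19/CYP1A2 perpetrator.
# Interaction constants are the network's library values; PK parameters
# (clearances, Km/Vmax, fu, Kp) are literature-plausible placeholders,
# NOT fitted values.
schema: pbpkddi-drug/1
name: fluvoxamine
molecular_weight: 318.33
fu: 0.23
blood_plasma_ratio: 1.0
kp_map:
  default: 15
  adipose: 40
pathways:
- enzyme: CYP2D6
  kinetics: saturable
  vmax: 1.17 1/min
  km: 0.1 uM
- enzyme: CYP1A2
  kinetics: linear
  cl_int: 1.38 L/min
inhibitions:
- target_enzyme: CYP1A2
  mechanism: competitive
  ki: 2.97 nM
  basis: in_vivo_unbound
- target_enzyme: CYP2C19
  mechanism: competitive
  ki: 3.6 nM
  basis: in_vivo_unbound
absorption:
  ka: 0.02 1/min
  f_abs: 1.0
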