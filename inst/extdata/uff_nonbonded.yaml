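# UFF nonbonded parameters used by cspkit's default pair_params():
# x: LJ minimum distance x_I (Angstrom); sigma = x / 2^(1/6)
# d: well depth D_I (kcal/mol)
H:  {x: 2.886, d: 0.044}
C:  {x: 3.851, d: 0.105}
N:  {x: 3.660, d: 0.069}
O:  {x: 3.500, d: 0.060}
F:  {x: 3.364, d: 0.050}
S:  {x: 4.035, d: 0.274}
Cl: {x: 3.947, d: 0.227}
Br: {x: 4.189, d: 0.251}
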