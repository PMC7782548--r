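ligand,calc,calc_err,exp
G1,-6.31,0.06,-5.24
G2,-6.19,0.08,-5.04
G3,-6.27,0.07,-5.94
G4,-2.51,0.07,-2.38
G5,-3.91,0.09,-3.90
G6,-4.97,0.07,-4.52
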