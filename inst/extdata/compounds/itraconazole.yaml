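name: itraconazole
molecular_weight: 705.64
fu_plasma: 0.002
bp_ratio_ref: 0.58
hct_ref: 0.45
fa: 1.0
ka: 0.5
fu_gut: 1.0
clint_cyp3a4_liver: 8029.0
clint_cyp3a5_liver: 0.0
clint_cyp3a4_gut: 6.83
clint_cyp3a5_gut: 0.0
cl_renal: 0.0
vss: 13.0
k12: 0.3
k21: 0.15
ki_cyp3a4: 6.0
ki_cyp3a5: 6.0
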