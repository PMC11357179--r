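name: tacrolimus
molecular_weight: 804.02
fu_plasma: 0.01
bp_ratio_ref: 15.0
hct_ref: 0.45
fa: 0.66
ka: 0.7
fu_gut: 1.0
clint_cyp3a4_liver: 3040.0
clint_cyp3a5_liver: 4762.0
clint_cyp3a4_gut: 25.5
clint_cyp3a5_gut: 25.8
cl_renal: 0.0
vss: 1.3
k12: 2.0
k21: 0.12
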