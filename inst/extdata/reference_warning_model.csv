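term,coefficient,variable_index
X1,0.3264,228
X2,0.3708,309
X3,0.0248,622
X4,0.0363,726
X5,-0.0008,1064
X6,-0.0005,1126
X7,-0.0014,1188
X8,0.4734,1526
X9,0.3338,1538
X10,0.0248,1861
X11,-0.0136,1889
X12,-0.0118,1894
X13,-0.0132,1974
X14,0.3407,2001
X15,-1.9581,2159
X16,0.3719,2163
X17,0.5173,2274
X18,-1.9010,2561
X19,0.0013,2758
X20,-0.0009,2965
intercept,38.9899,NA
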