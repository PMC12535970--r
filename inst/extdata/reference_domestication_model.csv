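term,b,se,z,or,ci_lo,ci_hi,p
Intercept,0.380,0.257,1.48,1.46,0.90,2.48,0.138
RC3,-0.249,0.241,-1.03,0.78,0.48,1.24,0.302
RC6,-0.551,0.249,-2.21,0.58,0.34,0.93,0.027
RC1,0.140,0.245,0.57,1.15,0.71,1.88,0.569
RC4,1.214,0.606,2.00,3.37,1.18,13.20,0.045
RC2,-0.645,0.272,-2.37,0.53,0.30,0.87,0.018
RC5,-0.170,0.238,-0.72,0.84,0.52,1.34,0.475
RC7,-0.611,0.266,-2.30,0.54,0.31,0.89,0.021
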