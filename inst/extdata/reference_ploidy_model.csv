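term,b,se,t,or,ci_lo,ci_hi
RC3,0.222,0.21,1.06,1.25,0.83,1.90
RC4,-0.286,0.30,-0.95,0.75,0.33,1.21
RC6,0.060,0.21,0.29,1.06,0.71,1.59
RC1,0.239,0.21,1.12,1.27,0.84,1.95
RC2,0.076,0.21,0.36,1.08,0.72,1.65
RC5,0.142,0.20,0.70,1.15,0.78,1.74
RC7,0.214,0.21,1.01,1.24,0.82,1.90
diploid|tetraploid,-0.076,0.22,-0.34,NA,NA,NA
tetraploid|hexaploid,1.167,0.26,4.49,NA,NA,NA
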