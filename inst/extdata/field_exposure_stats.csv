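metal,zone,n,gm,gsd
Cr,NF,18,0.064,2.68
Fe,NF,18,5.31,1.93
Mn,NF,18,1.38,1.97
Ni,NF,18,0.011,2.34
Pb,NF,18,0.008,2.28
Cr,FF,18,0.013,2.44
Fe,FF,18,1.06,2.58
Mn,FF,18,0.196,2.16
Ni,FF,18,0.001,2.17
Pb,FF,18,0.005,2.56
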