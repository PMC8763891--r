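metal,zone,n,gm,gsd
Cr,NF,25,0.008,1.32
Fe,NF,25,6.13,1.35
Mn,NF,25,0.236,1.16
Ni,NF,25,0.009,1.92
Pb,NF,25,0.003,1.41
Cr,FF,25,0.005,1.09
Fe,FF,25,1.22,1.08
Mn,FF,25,0.098,1.06
Ni,FF,25,0.003,1.11
Pb,FF,25,0.002,1.08
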