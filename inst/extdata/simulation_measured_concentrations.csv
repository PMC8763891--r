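metal,process,wire,current,zone,conc_mg_m3
Cr,FCAW,KFX71T,120,NF,0.007
Cr,FCAW,KFX71T,120,FF,0.002
Cr,FCAW,KFX70T,120,NF,0.011
Cr,FCAW,KFX70T,120,FF,0.004
Cr,GMAW,KM56,120,NF,0.003
Cr,GMAW,KM56,120,FF,0.001
Cr,GMAW,KM58,120,NF,0.004
Cr,GMAW,KM58,120,FF,0.002
Cr,FCAW,KFX71T,220,NF,0.008
Cr,FCAW,KFX71T,220,FF,0.004
Cr,FCAW,KFX70T,220,NF,0.016
Cr,FCAW,KFX70T,220,FF,0.007
Cr,GMAW,KM56,220,NF,0.004
Cr,GMAW,KM56,220,FF,0.002
Cr,GMAW,KM58,220,NF,0.005
Cr,GMAW,KM58,220,FF,0.002
Cr,FCAW,KFX71T,300,NF,0.011
Cr,FCAW,KFX71T,300,FF,0.005
Cr,FCAW,KFX70T,300,NF,0.018
Cr,FCAW,KFX70T,300,FF,0.009
Cr,GMAW,KM56,300,NF,0.006
Cr,GMAW,KM56,300,FF,0.003
Cr,GMAW,KM58,300,NF,0.006
Cr,GMAW,KM58,300,FF,0.003
Fe,FCAW,KFX71T,120,NF,22.9
Fe,FCAW,KFX71T,120,FF,7.15
Fe,FCAW,KFX70T,120,NF,20.6
Fe,FCAW,KFX70T,120,FF,8.21
Fe,GMAW,KM56,120,NF,16.1
Fe,GMAW,KM56,120,FF,5.95
Fe,GMAW,KM58,120,NF,20.5
Fe,GMAW,KM58,120,FF,7.69
Fe,FCAW,KFX71T,220,NF,26.9
Fe,FCAW,KFX71T,220,FF,13.6
Fe,FCAW,KFX70T,220,NF,30.7
Fe,FCAW,KFX70T,220,FF,13.2
Fe,GMAW,KM56,220,NF,20
Fe,GMAW,KM56,220,FF,9.17
Fe,GMAW,KM58,220,NF,23.4
Fe,GMAW,KM58,220,FF,11.4
Fe,FCAW,KFX71T,300,NF,37.9
Fe,FCAW,KFX71T,300,FF,17.8
Fe,FCAW,KFX70T,300,NF,34.5
Fe,FCAW,KFX70T,300,FF,17.1
Fe,GMAW,KM56,300,NF,29.1
Fe,GMAW,KM56,300,FF,15.6
Fe,GMAW,KM58,300,NF,28.7
Fe,GMAW,KM58,300,FF,15.8
Mn,FCAW,KFX71T,120,NF,0.184
Mn,FCAW,KFX71T,120,FF,0.057
Mn,FCAW,KFX70T,120,NF,0.261
Mn,FCAW,KFX70T,120,FF,0.104
Mn,GMAW,KM56,120,NF,0.241
Mn,GMAW,KM56,120,FF,0.089
Mn,GMAW,KM58,120,NF,0.308
Mn,GMAW,KM58,120,FF,0.116
Mn,FCAW,KFX71T,220,NF,0.215
Mn,FCAW,KFX71T,220,FF,0.108
Mn,FCAW,KFX70T,220,NF,0.389
Mn,FCAW,KFX70T,220,FF,0.168
Mn,GMAW,KM56,220,NF,0.301
Mn,GMAW,KM56,220,FF,0.138
Mn,GMAW,KM58,220,NF,0.351
Mn,GMAW,KM58,220,FF,0.172
Mn,FCAW,KFX71T,300,NF,0.303
Mn,FCAW,KFX71T,300,FF,0.142
Mn,FCAW,KFX70T,300,NF,0.438
Mn,FCAW,KFX70T,300,FF,0.217
Mn,GMAW,KM56,300,NF,0.438
Mn,GMAW,KM56,300,FF,0.234
Mn,GMAW,KM58,300,NF,0.431
Mn,GMAW,KM58,300,FF,0.238
Ni,FCAW,KFX71T,120,NF,0.005
Ni,FCAW,KFX71T,120,FF,0.001
Ni,FCAW,KFX70T,120,NF,0.011
Ni,FCAW,KFX70T,120,FF,0.004
Ni,GMAW,KM56,120,NF,0.003
Ni,GMAW,KM56,120,FF,0.001
Ni,GMAW,KM58,120,NF,0.004
Ni,GMAW,KM58,120,FF,0.002
Ni,FCAW,KFX71T,220,NF,0.005
Ni,FCAW,KFX71T,220,FF,0.003
Ni,FCAW,KFX70T,220,NF,0.016
Ni,FCAW,KFX70T,220,FF,0.007
Ni,GMAW,KM56,220,NF,0.004
Ni,GMAW,KM56,220,FF,0.002
Ni,GMAW,KM58,220,NF,0.005
Ni,GMAW,KM58,220,FF,0.002
Ni,FCAW,KFX71T,300,NF,0.008
Ni,FCAW,KFX71T,300,FF,0.004
Ni,FCAW,KFX70T,300,NF,0.018
Ni,FCAW,KFX70T,300,FF,0.009
Ni,GMAW,KM56,300,NF,0.006
Ni,GMAW,KM56,300,FF,0.003
Ni,GMAW,KM58,300,NF,0.006
Ni,GMAW,KM58,300,FF,0.003
Pb,FCAW,KFX71T,120,NF,0.005
Pb,FCAW,KFX71T,120,FF,0.001
Pb,FCAW,KFX70T,120,NF,0.008
Pb,FCAW,KFX70T,120,FF,0.003
Pb,GMAW,KM56,120,NF,0.003
Pb,GMAW,KM56,120,FF,0.001
Pb,GMAW,KM58,120,NF,0.004
Pb,GMAW,KM58,120,FF,0.002
Pb,FCAW,KFX71T,220,NF,0.005
Pb,FCAW,KFX71T,220,FF,0.003
Pb,FCAW,KFX70T,220,NF,0.012
Pb,FCAW,KFX70T,220,FF,0.005
Pb,GMAW,KM56,220,NF,0.004
Pb,GMAW,KM56,220,FF,0.002
Pb,GMAW,KM58,220,NF,0.005
Pb,GMAW,KM58,220,FF,0.002
Pb,FCAW,KFX71T,300,NF,0.008
Pb,FCAW,KFX71T,300,FF,0.004
Pb,FCAW,KFX70T,300,NF,0.014
Pb,FCAW,KFX70T,300,FF,0.007
Pb,GMAW,KM56,300,NF,0.006
Pb,GMAW,KM56,300,FF,0.003
Pb,GMAW,KM58,300,NF,0.006
Pb,GMAW,KM58,300,FF,0.003
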