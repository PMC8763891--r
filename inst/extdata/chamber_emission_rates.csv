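metal,process,wire,current,er_mg_min,cv,n
Cr,FCAW,KFX71T,120,0.02,0.87,3
Cr,FCAW,KFX70T,120,0.03,0.88,3
Cr,GMAW,KM56,120,0.02,2.16,3
Cr,GMAW,KM58,120,0.03,1.11,3
Cr,FCAW,KFX71T,220,0.04,1.96,3
Cr,FCAW,KFX70T,220,0.04,1.62,3
Cr,GMAW,KM56,220,0.03,1.24,3
Cr,GMAW,KM58,220,0.03,1.92,3
Cr,FCAW,KFX71T,300,0.07,1.23,3
Cr,FCAW,KFX70T,300,0.09,3.01,3
Cr,GMAW,KM56,300,0.06,2.16,3
Cr,GMAW,KM58,300,0.09,1.34,3
Fe,FCAW,KFX71T,120,25.2,1.26,3
Fe,FCAW,KFX70T,120,27.9,0.92,3
Fe,GMAW,KM56,120,20.5,1.88,3
Fe,GMAW,KM58,120,24.7,2.46,3
Fe,FCAW,KFX71T,220,31.8,1.85,3
Fe,FCAW,KFX70T,220,36.2,1.14,3
Fe,GMAW,KM56,220,29.4,2.85,3
Fe,GMAW,KM58,220,35.1,1.92,3
Fe,FCAW,KFX71T,300,69.8,1.02,3
Fe,FCAW,KFX70T,300,72.9,1.26,3
Fe,GMAW,KM56,300,64.7,2.16,3
Fe,GMAW,KM58,300,67.8,1.92,3
Mn,FCAW,KFX71T,120,1.91,1.03,3
Mn,FCAW,KFX70T,120,3.91,1.25,3
Mn,GMAW,KM56,120,1.93,2.25,3
Mn,GMAW,KM58,120,3.06,1.48,3
Mn,FCAW,KFX71T,220,3.39,2.62,3
Mn,FCAW,KFX70T,220,6.23,1.93,3
Mn,GMAW,KM56,220,2.65,2.81,3
Mn,GMAW,KM58,220,3.45,2.07,3
Mn,FCAW,KFX71T,300,8.01,1.44,3
Mn,FCAW,KFX70T,300,9.35,1.94,3
Mn,GMAW,KM56,300,7.94,1.24,3
Mn,GMAW,KM58,300,8.78,1.05,3
Ni,FCAW,KFX71T,120,0.02,2.04,3
Ni,FCAW,KFX70T,120,0.03,0.82,3
Ni,GMAW,KM56,120,0.03,2.14,3
Ni,GMAW,KM58,120,0.03,3.41,3
Ni,FCAW,KFX71T,220,0.05,3.98,3
Ni,FCAW,KFX70T,220,0.08,1.62,3
Ni,GMAW,KM56,220,0.04,2.15,3
Ni,GMAW,KM58,220,0.05,1.81,3
Ni,FCAW,KFX71T,300,0.11,2.83,3
Ni,FCAW,KFX70T,300,0.11,2.01,3
Ni,GMAW,KM56,300,0.06,3.66,3
Ni,GMAW,KM58,300,0.09,1.86,3
Pb,FCAW,KFX71T,120,0.02,1.45,3
Pb,FCAW,KFX70T,120,0.03,0.99,3
Pb,GMAW,KM56,120,0.02,2.49,3
Pb,GMAW,KM58,120,0.02,2.58,3
Pb,FCAW,KFX71T,220,0.04,2.48,3
Pb,FCAW,KFX70T,220,0.03,1.4,3
Pb,GMAW,KM56,220,0.03,2.46,3
Pb,GMAW,KM58,220,0.03,2.01,3
Pb,FCAW,KFX71T,300,0.09,2.07,3
Pb,FCAW,KFX70T,300,0.1,1.49,3
Pb,GMAW,KM56,300,0.06,1.64,3
Pb,GMAW,KM58,300,0.08,1.02,3
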