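group,soil,metal,day,worm_conc,soil_conc
Pb1,cambosol,Pb,1,0.76,152.23
Pb1,cambosol,Pb,7,1.23,152.23
Pb1,cambosol,Pb,14,1.75,152.23
Pb2,cambosol,Pb,1,1.72,324.99
Pb2,cambosol,Pb,7,2.43,324.99
Pb2,cambosol,Pb,14,7.52,324.99
Pb1,ferrosol,Pb,1,0.97,133.20
Pb1,ferrosol,Pb,7,9.26,133.20
Pb1,ferrosol,Pb,14,26.46,133.20
Pb2,ferrosol,Pb,1,1.86,248.67
Pb2,ferrosol,Pb,7,34.72,248.67
Pb2,ferrosol,Pb,14,66.24,248.67
Cd1,ferrosol,Cd,1,4.69,0.252
Cd1,ferrosol,Cd,7,5.59,0.252
Cd1,ferrosol,Cd,14,5.93,0.252
Cd2,ferrosol,Cd,1,5.33,0.524
Cd2,ferrosol,Cd,7,7.12,0.524
Cd2,ferrosol,Cd,14,9.45,0.524
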