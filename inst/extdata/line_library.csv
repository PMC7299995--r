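element,line,energy_keV,rel_intensity,sensitivity
Mg,Ka,1.253,0.88,0.00112
Mg,Kb,1.302,0.12,0.00112
Si,Ka,1.740,0.88,0.00165
Si,Kb,1.836,0.12,0.00165
Cl,Ka,2.622,0.88,0.00268
Cl,Kb,2.816,0.12,0.00268
Ar,Ka,2.958,0.88,0.00309
Ar,Kb,3.190,0.12,0.00309
Ca,Ka,3.692,0.88,0.00402
Ca,Kb,4.013,0.12,0.00402
Ti,Ka,4.511,0.88,0.00510
Ti,Kb,4.932,0.12,0.00510
V,Ka,4.952,0.88,0.00570
V,Kb,5.427,0.12,0.00570
Cr,Ka,5.415,0.88,0.00634
Cr,Kb,5.947,0.12,0.00634
Mn,Ka,5.899,0.88,0.00702
Mn,Kb,6.490,0.12,0.00702
Fe,Ka,6.404,0.88,0.00774
Fe,Kb,7.058,0.12,0.00774
Ni,Ka,7.478,0.88,0.00932
Ni,Kb,8.265,0.12,0.00932
Cu,Ka,8.048,0.88,0.01018
Cu,Kb,8.905,0.12,0.01018
Zn,Ka,8.639,0.88,0.01108
Zn,Kb,9.572,0.12,0.01108
As,Ka,10.544,0.88,0.01406
As,Kb,11.726,0.12,0.01406
Se,Ka,11.222,0.88,0.01514
Se,Kb,12.496,0.12,0.01514
Kr,Ka,12.649,0.88,0.01747
Kr,Kb,14.113,0.12,0.01747
Sr,Ka,14.098,0.88,0.02000
Sr,Kb,15.836,0.12,0.02000
W,La,8.398,0.75,0.00800
W,Lb,9.672,0.25,0.00800
Pb,La,10.552,0.75,0.01000
Pb,Lb,12.614,0.25,0.01000
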