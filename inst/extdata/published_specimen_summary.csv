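# Published per-specimen XRF summary statistics for cultured coccoliths
# (control C, medium M and high H metal-enrichment experiments).
# Molar ratios in mmol/mol; concentrations in ppm. Empty cells were either
# not detected or not unambiguously machine-readable from the printed table.
# Se/Ca of Go-M1 and Go-H1 is excluded upstream (badly resolved peak) and
# left empty here.
experiment,specimen,species,n_points,sr_ca,se_ca,as_ca,cl_ca,fe_ca,zn_ca,ni_ca,ca_ppm,sr_ppm
C,Cp4,C. pelagicus,30026,3.39,0.045,0.094,124,2.54,,0.49,165000,1170
C,Cp7,C. pelagicus,20202,4.03,0.049,0.098,103,2.04,,0.62,128000,1110
M,Cp-M1,C. pelagicus,17574,3.64,0.036,0.091,549,32.49,7.12,2.75,89300,704
M,Cp-M2,C. pelagicus,35938,5.07,0.043,0.109,619,4.65,5.80,2.96,73600,870
H,Cp-H1,C. pelagicus,34158,10.10,0.472,0.517,512,15.20,,1.21,66300,1060
H,Cp-H2,C. pelagicus,16528,5.10,0.218,0.271,,,,,115000,1120
H,Cp-H6,C. pelagicus,7142,5.35,0.127,0.147,,,,0.61,98000,1050
M,Go-M1,G. oceanica,3294,4.45,,,1570,3.53,,,37400,336
H,Go-H1,G. oceanica,5538,6.31,,,1985,3.94,,,28200,321
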