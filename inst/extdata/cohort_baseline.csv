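participant,group,phenotype,age_years,weight_kg,height_cm,bmi_kg_m2,ctg_repeats,ncam_pos_pct
Unaffected_1,unaffected,NA,24,54.0,165,19.8,NA,0.35
Unaffected_2,unaffected,NA,32,68.0,170,23.5,NA,0.31
Unaffected_3,unaffected,NA,22,61.2,159,24.2,NA,NA
Unaffected_4,unaffected,NA,25,70.3,165,25.8,NA,2.40
Unaffected_5,unaffected,NA,59,67.2,159,26.7,NA,0.94
Unaffected_6,unaffected,NA,58,52.2,157,21.3,NA,0.75
Unaffected_7,unaffected,NA,57,58.8,165,21.5,NA,0.88
Unaffected_8,unaffected,NA,63,74.1,159,29.3,NA,0
Unaffected_9,unaffected,NA,60,56.1,162,21.4,NA,NA
P1,DM1,Juvenile,52,56.0,150,24.9,509,7.14
P2,DM1,Juvenile,33,52.5,158,21.0,462,0
P3,DM1,Juvenile,33,40.0,168,14.2,832,61.35
P4,DM1,Late,39,80.2,167,28.8,70,0.69
P5,DM1,Adult,52,42.8,165,15.7,466,8.70
P6,DM1,Juvenile,24,47.6,162,18.1,488,6.96
P7,DM1,Adult,37,78.5,153,33.5,432,2.07
P8,DM1,Juvenile,25,80.0,161,30.9,300,1.15
P9,DM1,Adult,30,84.3,161,32.5,324,1.39
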