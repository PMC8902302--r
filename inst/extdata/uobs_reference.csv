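study,site,u_obs,u_ir
AGBRESA,MUSCLE_38,18.85,18.12
AGBRESA,MUSCLE_66,19.96,18.77
AGBRESA,TIBIA_04,0.73,0.63
AGBRESA,TIBIA_38,0.17,0.06
AGBRESA,TIBIA_66,0.31,0.28
AGBRESA,TIBIA_98,2.39,1.79
BBR,MUSCLE_66,23.56,20.63
BBR,TIBIA_04,4.27,3.89
BBR,TIBIA_38,1.20,1.10
BBR,TIBIA_66,0.21,0.06
LTBR,MUSCLE_66,5.37,2.42
LTBR,TIBIA_04,23.62,23.25
LTBR,TIBIA_66,0.89,0.75
MEP,TIBIA_04,0.61,0.24
MEP,TIBIA_38,0.18,0.08
MEP,TIBIA_66,0.08,-0.07
NUC,TIBIA_04,0.40,0.02
NUC,TIBIA_38,0.12,0.02
NUC,TIBIA_66,0.18,0.04
Planhab,MUSCLE_66,6.36,3.41
Planhab,TIBIA_04,2.81,2.74
Planhab,TIBIA_38,5.88,5.86
Planhab,TIBIA_66,1.04,0.89
Planhab,TIBIA_98,9.20,7.28
RSL,MUSCLE_38,9.35,8.62
RSL,MUSCLE_66,11.30,10.10
RSL,TIBIA_04,2.81,2.72
RSL,TIBIA_38,1.01,0.91
RSL,TIBIA_66,0.32,0.29
RSL,TIBIA_98,2.32,1.72
Valdoltra,TIBIA_04,1.22,1.15
Valdoltra,TIBIA_38,0.73,0.72
Valdoltra,TIBIA_98,6.37,4.44
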