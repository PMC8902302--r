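study,site,u_meas
RSL,MUSCLE_38,0.73
LTBR,MUSCLE_66,2.95
RSL,MUSCLE_66,1.20
LTBR,TIBIA_04,0.38
Valdoltra,TIBIA_04,0.08
RSL,TIBIA_04,0.09
Valdoltra,TIBIA_38,0.02
RSL,TIBIA_38,0.10
LTBR,TIBIA_66,0.15
RSL,TIBIA_66,0.03
Valdoltra,TIBIA_98,1.92
RSL,TIBIA_98,0.60
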