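landmark,x,y
snout_tip,0.00,0.00
eye_posterior,0.90,0.35
head_top,1.60,0.75
dorsal_fin_anterior,3.80,1.05
dorsal_fin_posterior,5.00,0.95
peduncle_dorsal,7.60,0.45
caudal_base_upper,8.30,0.55
caudal_fork,9.20,0.00
caudal_base_lower,8.30,-0.50
peduncle_ventral,7.60,-0.40
anal_fin_posterior,6.60,-0.65
anal_fin_anterior,5.90,-0.75
pelvic_fin_base,3.90,-0.95
pectoral_fin_base,2.20,-0.75
head_ventral,1.10,-0.50
lower_jaw_tip,0.25,-0.25
eye_centre,0.75,0.15
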