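patient_id,age_years,sex,black_race,scr_mg_dl,weight_kg,renal_modality
p001,50,M,0,1.0,78,none
p002,64,F,1,2.2,55,none
p003,41,M,0,0.7,120,none
p004,72,F,0,3.8,92,ihd
p005,58,M,0,1.6,103,none
p006,35,F,0,0.9,64,crrt
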