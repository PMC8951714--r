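patient_id,age_years,first_icu_stay,icu_los_hours,sepsis,death_28d
p1,17,1,48,0,0
p2,50,0,48,1,1
p3,60,1,48,0,0
p4,55,1,20,1,0
p5,70,1,48,1,1
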