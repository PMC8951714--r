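patient_id,time_hours,lactate_mmol_l
p1,2,2.1
p1,8,1.9
p1,15,1.8
p2,1,3.5
p2,6,3.0
p2,12,2.4
p3,5,2.5
p4,3,4.0
p4,9,3.2
p4,18,2.8
p5,2,4.5
p5,10,3.1
p5,20,2.2
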