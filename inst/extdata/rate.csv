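"study_id","treatment_code","y","person_years"
"study_01",1,55,124.052052206859
"study_01",2,50,148.29210838521
"study_02",1,8,52.9223439971246
"study_02",3,21,67.2963139716523
"study_03",1,47,58.9054356113955
"study_03",2,69,39.7705488841269
"study_05",1,50,87.7627712924175
"study_05",2,56,85.8124874859193
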