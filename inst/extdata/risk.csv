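"study_id","treatment_code","r","n","followup","followup_unit"
"study_01",1,47,174,0.712942828775049,"years"
"study_01",2,44,208,0.712942828775049,"years"
"study_02",1,8,162,0.32668113578472,"years"
"study_02",3,18,206,0.32668113578472,"years"
"study_03",1,38,157,0.375193857397423,"years"
"study_03",2,50,106,0.375193857397423,"years"
"study_04",1,69,220,0.701325180189046,"years"
"study_04",3,39,124,0.701325180189046,"years"
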