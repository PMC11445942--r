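component,variable,min,max,support,score
respiration,pf_ratio,400,Inf,none,0
respiration,pf_ratio,300,400,none,1
respiration,pf_ratio,200,300,none,2
respiration,pf_ratio,0,200,none,2
respiration,pf_ratio,100,200,vent,3
respiration,pf_ratio,0,100,vent,4
coagulation,platelets,150,Inf,none,0
coagulation,platelets,100,150,none,1
coagulation,platelets,50,100,none,2
coagulation,platelets,20,50,none,3
coagulation,platelets,0,20,none,4
hepatic,bilirubin_total,0,1.2,none,0
hepatic,bilirubin_total,1.2,2,none,1
hepatic,bilirubin_total,2,6,none,2
hepatic,bilirubin_total,6,12,none,3
hepatic,bilirubin_total,12,Inf,none,4
cardiovascular,map,70,Inf,none,0
cardiovascular,map,0,70,none,1
cardiovascular,dopamine,1e-9,5.000000001,none,2
cardiovascular,dobutamine,1e-9,Inf,none,2
cardiovascular,dopamine,5.000000001,15.000000001,none,3
cardiovascular,norepinephrine,1e-9,0.100000001,none,3
cardiovascular,epinephrine,1e-9,0.100000001,none,3
cardiovascular,dopamine,15.000000001,Inf,none,4
cardiovascular,norepinephrine,0.100000001,Inf,none,4
cardiovascular,epinephrine,0.100000001,Inf,none,4
cns,gcs_total,15,16,none,0
cns,gcs_total,13,15,none,1
cns,gcs_total,10,13,none,2
cns,gcs_total,6,10,none,3
cns,gcs_total,0,6,none,4
renal,creatinine,0,1.2,none,0
renal,creatinine,1.2,2,none,1
renal,creatinine,2,3.5,none,2
renal,creatinine,3.5,5,none,3
renal,creatinine,5,Inf,none,4
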