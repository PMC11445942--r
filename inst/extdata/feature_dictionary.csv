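feature,kind,family,healthy,lower,upper,missingness,block,ill_median,ill_q1,ill_q3,unit
heart_rate,vital,truncnorm,78,20,300,0.02,hemodynamic,96,83,110,bpm
resp_rate,vital,truncnorm,16,4,80,0.02,respiratory,23,18,28,breaths/min
temperature,vital,truncnorm,36.8,30,45,0.05,none,37.1,36.6,37.9,degC
spo2,vital,truncnorm,97,40,100,0.02,respiratory,95,91,98,%
sbp,vital,truncnorm,118,40,300,0.02,hemodynamic,118,107,131,mmHg
dbp,vital,truncnorm,70,20,200,0.02,hemodynamic,66,59,74,mmHg
map,vital,truncnorm,85,30,250,0.02,hemodynamic,82,75,90.2,mmHg
gcs_total,vital,truncnorm,15,3,15,0.1,none,14,12,15,points
pf_ratio,lab,lognormal,400,20,700,0.1,respiratory,240,162,334.9,mmHg
sf_ratio,lab,lognormal,460,30,600,0.25,respiratory,245,188.5,315.6,ratio
fio2,lab,truncnorm,0.21,0.21,1,0.1,none,0.4,0.3,0.5,fraction
pao2,lab,lognormal,90,20,600,0.2,respiratory,94,77,124,mmHg
paco2,lab,lognormal,40,10,150,0.15,respiratory,37,32,43,mmHg
arterial_ph,lab,truncnorm,7.4,6.5,8,0.15,none,7.36,7.28,7.42,pH
sodium,lab,truncnorm,139,110,175,0.05,chem,138,134,142,mmol/L
potassium,lab,truncnorm,4,1.5,9,0.05,chem,4.1,3.7,4.7,mmol/L
chloride,lab,truncnorm,103,70,140,0.05,chem,104,99,109,mmol/L
bicarbonate,lab,truncnorm,24,5,50,0.05,chem,21,17,25,mmol/L
bun,lab,lognormal,14,1,250,0.08,renal,30,19,50,mg/dL
creatinine,lab,lognormal,0.9,0.1,40,0.05,renal,1.4,0.9,2.9,mg/dL
glucose,lab,lognormal,110,20,1500,0.05,chem,140,108,196,mg/dL
calcium,lab,truncnorm,9.2,4,16,0.08,chem,8.6,8,9.2,mg/dL
magnesium,lab,truncnorm,2,0.5,6,0.1,chem,2,1.7,2.3,mg/dL
phosphorus,lab,lognormal,3.5,0.5,15,0.1,chem,3.6,2.8,4.7,mg/dL
anion_gap,lab,truncnorm,10,0,40,0.08,chem,12,9,16,mmol/L
bilirubin_total,lab,lognormal,0.7,0.05,60,0.2,hepatic,0.7,0.5,1.4,mg/dL
ast,lab,lognormal,28,5,10000,0.2,hepatic,45,26,110,U/L
alt,lab,lognormal,25,5,10000,0.2,hepatic,35,20,80,U/L
alk_phos,lab,lognormal,80,10,2000,0.2,hepatic,95,66,150,U/L
albumin,lab,truncnorm,4,0.8,6.5,0.1,hepatic,3,2.6,3.5,g/dL
wbc,lab,lognormal,8,0.1,200,0.05,heme,12,8,17.5,1e3/uL
hemoglobin,lab,truncnorm,13,2,25,0.05,heme,9.8,8.2,12,g/dL
hematocrit,lab,truncnorm,39,6,75,0.05,heme,29.5,24.6,36,%
rbc,lab,truncnorm,4.5,1,9,0.05,heme,3.6,3,4.2,1e6/uL
platelets,lab,lognormal,250,1,1500,0.05,coag,184,110.2,265.8,1e3/uL
mcv,lab,truncnorm,90,50,140,0.05,heme,90,85,95,fL
rdw,lab,truncnorm,13.5,10,35,0.05,heme,15,13.6,17.2,%
neutrophils_pct,lab,truncnorm,62,0,100,0.15,heme,80,70,87,%
lymphocytes_pct,lab,truncnorm,26,0,100,0.15,heme,10,6,16,%
inr,lab,lognormal,1,0.4,20,0.2,coag,1.3,1.1,1.8,ratio
pt,lab,lognormal,12,5,120,0.2,coag,14.3,12.1,19.8,s
ptt,lab,lognormal,30,10,250,0.25,coag,33,28,43,s
d_dimer,lab,lognormal,400,50,100000,0.55,coag,2678.2,1141.2,9258.5,ng/mL
fibrinogen,lab,lognormal,350,30,1500,0.5,coag,420,290,580,mg/dL
bnp,lab,lognormal,60,1,70000,0.5,cardiac,328,100,915,pg/mL
troponin,lab,lognormal,0.02,0.001,1000,0.5,cardiac,0.05,0.015,0.25,ng/mL
lactate,lab,lognormal,1,0.2,30,0.15,none,1.6,1.2,2.6,mmol/L
weight_kg,lab,truncnorm,80,30,300,0.05,none,80,66,96,kg
ferritin,lab,lognormal,150,5,50000,0.6,none,600,250,1600,ng/mL
procalcitonin,lab,lognormal,0.1,0.01,5000,0.92,none,2,0.4,10,ng/mL
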