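category,icd9_prefix,weight,hierarchy_group
myocardial_infarction,410,1,none
myocardial_infarction,412,1,none
congestive_heart_failure,428,1,none
peripheral_vascular_disease,441,1,none
peripheral_vascular_disease,443.9,1,none
peripheral_vascular_disease,785.4,1,none
cerebrovascular_disease,430,1,none
cerebrovascular_disease,431,1,none
cerebrovascular_disease,432,1,none
cerebrovascular_disease,433,1,none
cerebrovascular_disease,434,1,none
cerebrovascular_disease,435,1,none
cerebrovascular_disease,436,1,none
cerebrovascular_disease,437,1,none
cerebrovascular_disease,438,1,none
dementia,290,1,none
chronic_pulmonary_disease,490,1,none
chronic_pulmonary_disease,491,1,none
chronic_pulmonary_disease,492,1,none
chronic_pulmonary_disease,493,1,none
chronic_pulmonary_disease,494,1,none
chronic_pulmonary_disease,495,1,none
chronic_pulmonary_disease,496,1,none
chronic_pulmonary_disease,500,1,none
chronic_pulmonary_disease,501,1,none
chronic_pulmonary_disease,502,1,none
chronic_pulmonary_disease,503,1,none
chronic_pulmonary_disease,504,1,none
chronic_pulmonary_disease,505,1,none
rheumatic_disease,710,1,none
rheumatic_disease,714,1,none
rheumatic_disease,725,1,none
peptic_ulcer_disease,531,1,none
peptic_ulcer_disease,532,1,none
peptic_ulcer_disease,533,1,none
peptic_ulcer_disease,534,1,none
mild_liver_disease,571.2,1,liver
mild_liver_disease,571.4,1,liver
mild_liver_disease,571.5,1,liver
mild_liver_disease,571.6,1,liver
diabetes_uncomplicated,250.0,1,diabetes
diabetes_uncomplicated,250.1,1,diabetes
diabetes_uncomplicated,250.2,1,diabetes
diabetes_uncomplicated,250.3,1,diabetes
diabetes_uncomplicated,250.7,1,diabetes
diabetes_complicated,250.4,2,diabetes
diabetes_complicated,250.5,2,diabetes
diabetes_complicated,250.6,2,diabetes
hemiplegia,342,2,none
hemiplegia,344.1,2,none
renal_disease,582,2,none
renal_disease,583,2,none
renal_disease,585,2,none
renal_disease,586,2,none
renal_disease,588,2,none
malignancy,140,2,cancer
malignancy,150,2,cancer
malignancy,151,2,cancer
malignancy,153,2,cancer
malignancy,155,2,cancer
malignancy,157,2,cancer
malignancy,162,2,cancer
malignancy,174,2,cancer
malignancy,185,2,cancer
malignancy,188,2,cancer
malignancy,189,2,cancer
malignancy,200,2,cancer
malignancy,201,2,cancer
malignancy,202,2,cancer
malignancy,203,2,cancer
malignancy,204,2,cancer
malignancy,205,2,cancer
malignancy,208,2,cancer
moderate_severe_liver_disease,456.0,3,liver
moderate_severe_liver_disease,456.1,3,liver
moderate_severe_liver_disease,456.2,3,liver
moderate_severe_liver_disease,572.2,3,liver
moderate_severe_liver_disease,572.3,3,liver
moderate_severe_liver_disease,572.4,3,liver
moderate_severe_liver_disease,572.8,3,liver
metastatic_solid_tumor,196,6,cancer
metastatic_solid_tumor,197,6,cancer
metastatic_solid_tumor,198,6,cancer
metastatic_solid_tumor,199.0,6,cancer
metastatic_solid_tumor,199.1,6,cancer
aids,042,6,none
aids,043,6,none
aids,044,6,none
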