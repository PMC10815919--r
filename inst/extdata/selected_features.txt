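patient_age
last_wbc_count
last_cretenine_preop
BPsystolic
last_hematocrit
cardiac_presentation_on_admission
statin
mitral_regurgitation
diastolic
gender_id
CABG_status
nitratesIV
family_history_of_cardiac_disease
beta_blockers
arrhythmia
lipid_lowering
prior_pci
cerebrovascular_disease
pulmonary_insufficiency
MI_timing
inotropes
angina_class
PCI_timing
congestive_heart_failure
adp_inhibitors_within_5days
cardiogenic_shock
intracardiac_device
pulmonary_artery_hypertension
NYHA_class
arrhythmia_type_sust_vt_vf
myocardial_infarction
resuscitation
dialysis
steroids
previous_coronary_bypass
previous_valve
first_cv_surgery
warfarin
ace_inhibitors
carotid_disease
aspirin
left_main_disease
bronchodilators
coronaries_diseased
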