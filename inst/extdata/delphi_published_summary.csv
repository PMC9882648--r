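item_id,item_kind,round,published_average,published_group
hip-fracture,health_state_event,1,4.89,inclusion
surgery-for-hip-fracture,health_state_event,1,4.80,inclusion
head-injury,health_state_event,1,4.70,inclusion
fall,health_state_event,1,4.60,inclusion
long-term-care-housing,health_state_event,1,4.40,inclusion
vertebral-fracture,health_state_event,1,4.40,inclusion
hospitalization,health_state_event,1,4.40,inclusion
rehabilitation-hospitalization,health_state_event,1,4.40,inclusion
specialized-dementia-care,health_state_event,1,4.20,inclusion
post-fall,health_state_event,1,4.20,non_consensus
wrist-fracture,health_state_event,1,4.00,non_consensus
emergency-department-visit,health_state_event,1,4.00,non_consensus
independent-housing,health_state_event,1,3.70,non_consensus
independent-supported-living,health_state_event,1,3.70,non_consensus
assisted-living,health_state_event,1,3.70,non_consensus
death-due-to-fall,health_state_event,1,3.73,non_consensus
short-term-stay-supportive-housing,health_state_event,1,3.50,non_consensus
death,health_state_event,1,3.55,non_consensus
fear-of-falling-state,health_state_event,1,3.50,non_consensus
no-fall-history,health_state_event,1,2.90,non_consensus
gait-balance-mobility,patient_attribute,1,5.00,inclusion
history-of-falls,patient_attribute,1,4.80,inclusion
impaired-vision,patient_attribute,1,4.50,inclusion
older-age,patient_attribute,1,4.36,inclusion
dementia-biological,patient_attribute,1,4.40,inclusion
physical-inactivity,patient_attribute,1,4.60,inclusion
fear-of-falling,patient_attribute,1,4.22,inclusion
substance-use,patient_attribute,1,4.10,inclusion
certain-medications,patient_attribute,1,4.80,inclusion
transfer-assistance,patient_attribute,1,4.40,inclusion
home-hazards,patient_attribute,1,4.30,inclusion
use-of-restraints,patient_attribute,1,4.20,inclusion
frailty,patient_attribute,1,4.60,inclusion
parkinsons-disease,patient_attribute,1,4.60,inclusion
stroke,patient_attribute,1,4.60,inclusion
dementia-condition,patient_attribute,1,4.50,inclusion
multiple-sclerosis,patient_attribute,1,4.44,inclusion
osteoporosis,patient_attribute,1,3.88,inclusion
malnutrition-sarcopenia,patient_attribute,1,3.88,non_consensus
sex,patient_attribute,1,3.43,non_consensus
incontinence,patient_attribute,1,3.33,non_consensus
hurrying-not-paying-attention,patient_attribute,1,3.80,non_consensus
incorrect-assistive-device-use,patient_attribute,1,3.80,non_consensus
dual-tasking,patient_attribute,1,3.67,non_consensus
unsupportive-footwear,patient_attribute,1,3.67,non_consensus
taking-risks,patient_attribute,1,3.60,non_consensus
gender,patient_attribute,1,2.67,non_consensus
polypharmacy,patient_attribute,1,4.20,non_consensus
prolonged-hospital-stay,patient_attribute,1,4.00,non_consensus
side-rails,patient_attribute,1,3.67,non_consensus
cannot-afford-footwear,patient_attribute,1,3.78,non_consensus
social-isolation,patient_attribute,1,3.80,non_consensus
cannot-afford-medications,patient_attribute,1,3.67,non_consensus
unable-to-read,patient_attribute,1,3.00,non_consensus
psychiatric-illness,patient_attribute,1,3.70,non_consensus
osteoarthritis,patient_attribute,1,3.38,non_consensus
cancer,patient_attribute,1,3.33,non_consensus
hemophilia,patient_attribute,1,3.00,non_consensus
post-fall,health_state_event,2,4.38,inclusion
wrist-fracture,health_state_event,2,3.89,inclusion
emergency-department-visit,health_state_event,2,4.10,inclusion
independent-housing,health_state_event,2,3.70,inclusion
death-due-to-fall,health_state_event,2,4.11,inclusion
independent-supported-living,health_state_event,2,3.70,non_consensus
assisted-living,health_state_event,2,3.70,non_consensus
short-term-stay-supportive-housing,health_state_event,2,3.40,non_consensus
death,health_state_event,2,3.78,non_consensus
fear-of-falling-state,health_state_event,2,3.44,non_consensus
no-fall-history,health_state_event,2,2.60,non_consensus
ankle-fracture,health_state_event,2,3.80,non_consensus
humerus-fracture,health_state_event,2,3.89,non_consensus
alternate-level-of-care,health_state_event,2,3.78,non_consensus
transitional-care-unit,health_state_event,2,3.78,non_consensus
incorrect-assistive-device-use,patient_attribute,2,4.00,inclusion
unsupportive-footwear,patient_attribute,2,4.00,inclusion
polypharmacy,patient_attribute,2,4.30,inclusion
prolonged-hospital-stay,patient_attribute,2,4.10,inclusion
cannot-afford-footwear,patient_attribute,2,3.89,inclusion
social-isolation,patient_attribute,2,4.00,inclusion
cannot-afford-medications,patient_attribute,2,3.90,inclusion
psychiatric-illness,patient_attribute,2,3.80,inclusion
malnutrition-sarcopenia,patient_attribute,2,3.89,non_consensus
sex,patient_attribute,2,3.30,non_consensus
incontinence,patient_attribute,2,3.40,non_consensus
hurrying-not-paying-attention,patient_attribute,2,3.78,non_consensus
dual-tasking,patient_attribute,2,3.56,non_consensus
taking-risks,patient_attribute,2,3.78,non_consensus
gender,patient_attribute,2,2.90,non_consensus
side-rails,patient_attribute,2,3.78,non_consensus
unable-to-read,patient_attribute,2,3.30,non_consensus
osteoarthritis,patient_attribute,2,3.40,non_consensus
cancer,patient_attribute,2,3.20,non_consensus
hemophilia,patient_attribute,2,3.10,non_consensus
diabetes,patient_attribute,2,3.70,non_consensus
cardiac-disease,patient_attribute,2,3.40,non_consensus
hypertension,patient_attribute,2,3.40,non_consensus
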