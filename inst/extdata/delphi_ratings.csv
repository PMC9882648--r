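item_id,item_label,item_kind,round,count_0,count_1,count_2,count_3,count_4,count_5,dont_know,n_respondents
hip-fracture,Hip fracture,health_state_event,1,0,0,0,0,1,8,2,11
surgery-for-hip-fracture,Surgery for hip fracture,health_state_event,1,0,0,0,0,2,8,1,11
head-injury,Head injury,health_state_event,1,0,0,0,1,1,8,1,11
fall,Fall,health_state_event,1,0,0,0,1,2,7,1,11
long-term-care-housing,"Long-term care housing (e.g., nursing home)",health_state_event,1,0,0,1,0,3,6,1,11
vertebral-fracture,Vertebral fracture,health_state_event,1,0,0,1,1,1,7,1,11
hospitalization,Hospitalization,health_state_event,1,0,0,1,1,1,7,1,11
rehabilitation-hospitalization,Rehabilitation hospitalization,health_state_event,1,0,0,0,0,6,4,1,11
specialized-dementia-care,"Specialized dementia care or memory care in supportive housing (e.g., retirement home)",health_state_event,1,0,0,1,1,3,5,1,11
post-fall,Post-fall,health_state_event,1,0,0,1,2,1,6,1,11
wrist-fracture,Wrist fracture,health_state_event,1,0,0,0,4,2,4,1,11
emergency-department-visit,Emergency department visit,health_state_event,1,0,1,0,2,2,5,1,11
independent-housing,"Independent housing (e.g., own home)",health_state_event,1,1,0,0,2,4,3,1,11
independent-supported-living,Independent supported living service in supportive housing,health_state_event,1,0,0,0,4,5,1,1,11
assisted-living,"Assisted living in supportive housing (e.g., retirement home)",health_state_event,1,0,0,0,4,5,1,1,11
death-due-to-fall,Death due to fall,health_state_event,1,1,2,0,0,1,7,0,11
short-term-stay-supportive-housing,"Short term stay in supportive housing (e.g., retirement home)",health_state_event,1,0,0,0,6,3,1,1,11
death,Death,health_state_event,1,1,2,0,1,1,6,0,11
fear-of-falling-state,Fear of falling,health_state_event,1,0,0,2,4,1,3,1,11
no-fall-history,No fall history,health_state_event,1,1,2,1,2,1,3,1,11
gait-balance-mobility,"Gait, balance, or mobility difficulties",patient_attribute,1,0,0,0,0,0,10,1,11
history-of-falls,History of falls/previous falls,patient_attribute,1,0,0,0,0,2,8,1,11
impaired-vision,Impaired vision,patient_attribute,1,0,0,0,1,3,6,1,11
older-age,"Age, older age",patient_attribute,1,0,0,0,1,5,5,0,11
dementia-biological,Dementia/cognitive impairment,patient_attribute,1,0,0,0,1,4,5,1,11
physical-inactivity,Physical inactivity,patient_attribute,1,0,0,0,0,4,6,1,11
fear-of-falling,Fear of falling,patient_attribute,1,0,0,0,1,5,3,2,11
substance-use,Substance use,patient_attribute,1,0,0,0,2,5,3,1,11
certain-medications,"Use of certain medications (anticonvulsants, tranquilizers, antihypertensives, opioids/narcotics)",patient_attribute,1,0,0,0,0,2,8,1,11
transfer-assistance,Need for transfer assistance,patient_attribute,1,0,0,0,0,6,4,1,11
home-hazards,"Home hazards (e.g., loose carpets, pets, stairs)",patient_attribute,1,0,0,0,1,5,4,1,11
use-of-restraints,Use of restraints,patient_attribute,1,0,0,1,0,5,4,1,11
frailty,"Overall frailty, older age",patient_attribute,1,0,0,0,0,4,6,1,11
parkinsons-disease,Parkinson's disease,patient_attribute,1,0,0,0,0,4,6,1,11
stroke,Stroke,patient_attribute,1,0,0,0,0,4,6,1,11
dementia-condition,Dementia/cognitive impairment,patient_attribute,1,0,0,0,0,5,5,1,11
multiple-sclerosis,Multiple sclerosis,patient_attribute,1,0,0,0,0,5,4,2,11
osteoporosis,Osteoporosis,patient_attribute,1,0,1,0,0,5,2,3,11
malnutrition-sarcopenia,Malnutrition and related sarcopenia,patient_attribute,1,0,0,0,3,3,2,3,11
sex,Sex,patient_attribute,1,0,0,0,5,1,1,4,11
incontinence,Incontinence,patient_attribute,1,0,0,1,4,4,0,2,11
hurrying-not-paying-attention,"Hurrying, not paying attention",patient_attribute,1,0,0,0,4,4,2,1,11
incorrect-assistive-device-use,Incorrect use of assistive devices,patient_attribute,1,0,0,0,4,4,2,1,11
dual-tasking,Dual tasking,patient_attribute,1,0,0,1,3,3,2,2,11
unsupportive-footwear,Wearing unsupportive footwear,patient_attribute,1,0,0,0,5,2,2,2,11
taking-risks,Taking risks,patient_attribute,1,0,0,0,4,6,0,1,11
gender,Gender,patient_attribute,1,0,0,3,2,1,0,5,11
polypharmacy,Polypharmacy,patient_attribute,1,0,0,1,2,1,6,1,11
prolonged-hospital-stay,Prolonged hospital stay,patient_attribute,1,0,0,0,2,5,2,2,11
side-rails,Side rails,patient_attribute,1,0,0,2,2,2,3,2,11
cannot-afford-footwear,Unable to afford supportive footwear,patient_attribute,1,0,0,0,3,5,1,2,11
social-isolation,"No social supports, isolated",patient_attribute,1,0,0,1,2,5,2,1,11
cannot-afford-medications,"Unable to afford certain medications, nutritious food",patient_attribute,1,0,0,0,4,4,1,2,11
unable-to-read,Unable to read,patient_attribute,1,1,1,1,2,2,2,2,11
psychiatric-illness,Psychiatric illness (including depression),patient_attribute,1,0,0,2,2,3,3,1,11
osteoarthritis,Osteoarthritis,patient_attribute,1,0,0,1,3,4,0,3,11
cancer,Cancer,patient_attribute,1,1,0,0,3,4,1,2,11
hemophilia,Hemophilia,patient_attribute,1,1,0,1,1,2,1,5,11
post-fall,Post-fall,health_state_event,2,0,0,0,0,5,3,2,10
wrist-fracture,Wrist fracture,health_state_event,2,0,0,0,1,8,0,1,10
emergency-department-visit,Emergency department visit,health_state_event,2,0,0,0,1,7,2,0,10
independent-housing,"Independent housing (e.g., own home)",health_state_event,2,0,0,1,1,8,0,0,10
death-due-to-fall,Death due to fall,health_state_event,2,0,0,0,1,6,2,1,10
independent-supported-living,Independent supported living service in supportive housing,health_state_event,2,0,0,0,3,7,0,0,10
assisted-living,"Assisted living in supportive housing (e.g., retirement home)",health_state_event,2,0,0,0,3,7,0,0,10
short-term-stay-supportive-housing,"Short term stay in supportive housing (e.g., retirement home)",health_state_event,2,0,0,0,6,4,0,0,10
death,Death,health_state_event,2,0,0,0,4,3,2,1,10
fear-of-falling-state,Fear of falling,health_state_event,2,0,0,0,5,4,0,1,10
no-fall-history,No fall history,health_state_event,2,0,1,3,5,1,0,0,10
ankle-fracture,Ankle fracture,health_state_event,2,0,0,0,4,4,2,0,10
humerus-fracture,Humerus fracture,health_state_event,2,0,0,0,2,6,1,1,10
alternate-level-of-care,Alternate level of care,health_state_event,2,0,0,0,4,3,2,1,10
transitional-care-unit,Transitional care unit,health_state_event,2,0,0,0,4,3,2,1,10
incorrect-assistive-device-use,Incorrect use of assistive devices,patient_attribute,2,0,0,0,1,8,1,0,10
unsupportive-footwear,Wearing unsupportive footwear,patient_attribute,2,0,0,0,0,9,0,1,10
polypharmacy,Polypharmacy,patient_attribute,2,0,0,0,0,7,3,0,10
prolonged-hospital-stay,Prolonged hospital stay,patient_attribute,2,0,0,0,0,9,1,0,10
cannot-afford-footwear,Unable to afford supportive footwear,patient_attribute,2,0,0,0,1,8,0,1,10
social-isolation,"No social supports, isolated",patient_attribute,2,0,0,0,0,10,0,0,10
cannot-afford-medications,"Unable to afford certain medications, nutritious food",patient_attribute,2,0,0,0,1,9,0,0,10
psychiatric-illness,Psychiatric illness (including depression),patient_attribute,2,0,0,0,2,8,0,0,10
malnutrition-sarcopenia,Malnutrition and related sarcopenia,patient_attribute,2,0,0,0,2,6,1,1,10
sex,Sex,patient_attribute,2,0,0,0,7,3,0,0,10
incontinence,Incontinence,patient_attribute,2,0,0,0,6,4,0,0,10
hurrying-not-paying-attention,"Hurrying, not paying attention",patient_attribute,2,0,0,0,2,7,0,1,10
dual-tasking,Dual tasking,patient_attribute,2,0,0,0,4,5,0,1,10
taking-risks,Taking risks,patient_attribute,2,0,0,0,2,7,0,1,10
gender,Gender,patient_attribute,2,0,0,2,7,1,0,0,10
side-rails,Side rails,patient_attribute,2,0,0,0,2,7,0,1,10
unable-to-read,Unable to read,patient_attribute,2,0,0,1,5,4,0,0,10
osteoarthritis,Osteoarthritis,patient_attribute,2,0,0,0,6,4,0,0,10
cancer,Cancer,patient_attribute,2,0,0,0,9,0,1,0,10
hemophilia,Hemophilia,patient_attribute,2,0,0,0,9,1,0,0,10
diabetes,Diabetes,patient_attribute,2,0,0,0,4,5,1,0,10
cardiac-disease,Cardiac disease,patient_attribute,2,0,0,1,5,3,1,0,10
hypertension,Hypertension,patient_attribute,2,0,0,0,6,4,0,0,10
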