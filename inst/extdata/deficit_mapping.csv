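ehr_deficit,survey_deficit,relation,note
visual_impairment,eyesight_difficulty,one_to_one,
fragility_fracture,fracture_since_50,one_to_one,
heart_failure,heart_failure_reported,one_to_one,
social_vulnerability,social_detachment,one_to_one,
diabetes,diabetes_or_high_blood_sugar,one_to_one,
hypertension,high_blood_pressure,one_to_one,
cerebrovascular_disease,stroke,one_to_one,
osteoporosis,osteoporosis_reported,one_to_one,
falls,fall_in_last_year,one_to_one,
sleep_disturbance,restless_sleep,one_to_one,
arthritis,arthritis_reported,one_to_one,
atrial_fibrillation,abnormal_heart_rhythm,one_to_one,
hearing_impairment,hearing_difficulty,one_to_one,
parkinsonism_and_tremor,parkinsons_disease,one_to_one,
mobility_and_transfer_problems,difficulty_walking_100m,one_to_many,
mobility_and_transfer_problems,difficulty_sitting_2_hours,one_to_many,placeholder
mobility_and_transfer_problems,difficulty_getting_up_from_chair,one_to_many,placeholder
mobility_and_transfer_problems,difficulty_climbing_several_flights,one_to_many,placeholder
mobility_and_transfer_problems,difficulty_climbing_one_flight,one_to_many,
mobility_and_transfer_problems,difficulty_stooping_kneeling,one_to_many,placeholder
mobility_and_transfer_problems,difficulty_reaching_above_shoulder,one_to_many,placeholder
mobility_and_transfer_problems,difficulty_pulling_pushing,one_to_many,placeholder
mobility_and_transfer_problems,difficulty_lifting_5kg,one_to_many,placeholder
mobility_and_transfer_problems,difficulty_picking_up_coin,one_to_many,placeholder
requirement_for_care,difficulty_dressing,one_to_many,
requirement_for_care,difficulty_walking_across_room,one_to_many,placeholder
requirement_for_care,difficulty_bathing,one_to_many,placeholder
requirement_for_care,difficulty_eating,one_to_many,
requirement_for_care,difficulty_getting_in_out_bed,one_to_many,placeholder
requirement_for_care,difficulty_using_toilet,one_to_many,placeholder
requirement_for_care,difficulty_preparing_hot_meal,one_to_many,placeholder
requirement_for_care,difficulty_taking_medications,one_to_many,placeholder
activity_limitation,difficulty_shopping_groceries,one_to_many,placeholder
activity_limitation,difficulty_telephone_calls,one_to_many,placeholder
activity_limitation,difficulty_managing_money,one_to_many,placeholder
activity_limitation,difficulty_housework_gardening,one_to_many,placeholder
activity_limitation,difficulty_using_map,one_to_many,placeholder
activity_limitation,limited_in_activities,one_to_many,placeholder
respiratory_disease,lung_disease,one_to_many,
respiratory_disease,asthma,one_to_many,
memory_and_cognitive_problems,self_rated_memory_poor,one_to_many,placeholder
memory_and_cognitive_problems,memory_worse_than_2_years_ago,one_to_many,placeholder
memory_and_cognitive_problems,date_orientation_errors,one_to_many,placeholder
weight_loss_and_anorexia,unintended_weight_loss,one_to_many,placeholder
weight_loss_and_anorexia,poor_appetite,one_to_many,placeholder
anaemia_and_haematinic_deficiency,,one_to_none,
chronic_kidney_disease,,one_to_none,
dizziness,,one_to_none,
dyspnoea,,one_to_none,
foot_problems,,one_to_none,
heart_valve_disease,,one_to_none,
housebound,,one_to_none,
hypotension_or_syncope,,one_to_none,
ischaemic_heart_disease,,one_to_none,
peptic_ulcer,,one_to_none,
peripheral_vascular_disease,,one_to_none,
polypharmacy,,one_to_none,
skin_ulcer,,one_to_none,
thyroid_disease,,one_to_none,
urinary_incontinence,,one_to_none,
urinary_system_disease,,one_to_none,
,sadness,one_to_none,
,loneliness,one_to_none,
,felt_depressed,one_to_none,
,everything_an_effort,one_to_none,
,could_not_get_going,one_to_none,
,not_enjoying_life,one_to_none,
,feeling_unhappy,one_to_none,
,poor_self_rated_health,one_to_none,
,long_standing_limiting_illness,one_to_none,
,cancer_diagnosis,one_to_none,
,high_cholesterol,one_to_none,
,dental_problems,one_to_none,
,psychiatric_problems,one_to_none,
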