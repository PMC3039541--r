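covariate,category,cohort_pct,reference_pct,cohort_n,reference_n
smoking,never_smoker,62.1,64.6,12423,894
smoking,ex_smoker,30.4,24.3,12423,894
smoking,current_smoker,7.6,11.0,12423,894
marital_status,partnered,55.6,49.6,12423,894
marital_status,separated_divorced,6.3,5.6,12423,894
marital_status,widowed,34.8,42.4,12423,894
marital_status,never_married,3.2,2.4,12423,894
country_of_birth,australia,73.5,74.2,12423,894
country_of_birth,other_english_speaking,13.6,10.9,12423,894
country_of_birth,europe,10.1,12.0,12423,894
country_of_birth,asia,1.8,1.4,12423,894
country_of_birth,other,1.0,1.6,12423,894
education,no_higher_qualification,84.0,79.3,12423,894
education,trade_certificate_diploma,11.7,16.7,12423,894
education,university,4.2,2.7,12423,894
bmi_group,underweight,3.2,4.2,12423,894
bmi_group,healthy_weight,50.4,52.1,12423,894
bmi_group,overweight,33.1,29.1,12423,894
bmi_group,obese,13.2,14.5,12423,894
self_rated_health,excellent,6.4,7.6,12423,894
self_rated_health,very_good,26.2,23.2,12423,894
self_rated_health,good,39.4,34.4,12423,894
self_rated_health,fair,23.6,24.3,12423,894
self_rated_health,poor,4.3,10.5,12423,894
walking_100m,limited_a_lot,7.1,11.3,12423,894
walking_100m,limited_a_little,15.4,19.7,12423,894
walking_100m,not_limited,77.4,68.9,12423,894
state,new_south_wales,34.9,35.8,12423,894
state,australian_capital_territory,1.1,0.8,12423,894
state,queensland,16.3,16.6,12423,894
state,south_australia,10.2,10.0,12423,894
state,tasmania,2.8,2.5,12423,894
state,victoria,26.0,25.9,12423,894
state,western_australia,8.5,8.5,12423,894
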