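characteristic,statistic,control,education,education_sms
enrolled,count,180,180,179
age_years,mean,39.1,44.0,40.1
age_years,sd,11.8,11.5,12.3
age_below_40,count,94,64,87
age_above_40,count,86,116,92
male,count,151,144,161
female,count,29,36,18
primary_or_below,count,81,116,85
above_primary,count,99,64,94
below_poverty,count,29,35,31
above_poverty,count,151,145,148
prior_training_no,count,127,132,108
prior_training_yes,count,53,48,71
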