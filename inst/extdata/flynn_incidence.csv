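sex,age_group,disease,rate,ci_lo,ci_hi
male,10-19,hypothyroidism,0.09,0.03,0.19
male,20-29,hypothyroidism,0.24,0.14,0.38
male,30-39,hypothyroidism,0.43,0.30,0.60
male,40-49,hypothyroidism,0.64,0.48,0.84
male,50-59,hypothyroidism,1.19,0.95,1.48
male,60-69,hypothyroidism,1.78,1.46,2.14
male,70-79,hypothyroidism,2.69,2.20,3.25
male,10-19,hyperthyroidism,0.03,0.00,0.05
male,20-29,hyperthyroidism,0.06,0.02,0.14
male,30-39,hyperthyroidism,0.13,0.07,0.23
male,40-49,hyperthyroidism,0.21,0.13,0.32
male,50-59,hyperthyroidism,0.18,0.10,0.30
male,60-69,hyperthyroidism,0.27,0.16,0.42
male,70-79,hyperthyroidism,0.29,0.15,0.49
female,10-19,hypothyroidism,0.35,0.22,0.53
female,20-29,hypothyroidism,1.83,1.53,2.19
female,30-39,hypothyroidism,3.39,3.01,3.82
female,40-49,hypothyroidism,6.07,5.55,6.62
female,50-59,hypothyroidism,7.78,7.14,8.46
female,60-69,hypothyroidism,9.06,8.37,9.79
female,70-79,hypothyroidism,8.84,8.08,9.65
female,10-19,hyperthyroidism,0.14,0.07,0.25
female,20-29,hyperthyroidism,0.78,0.60,1.01
female,30-39,hyperthyroidism,0.85,0.68,1.06
female,40-49,hyperthyroidism,0.90,0.72,1.14
female,50-59,hyperthyroidism,0.91,0.71,1.14
female,60-69,hyperthyroidism,1.12,0.90,1.38
female,70-79,hyperthyroidism,1.29,1.03,1.60
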