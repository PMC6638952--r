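sex,age_group,disease,rate,ci_lo,ci_hi
male,10-19,hypothyroidism,0.47,0.43,0.52
male,20-29,hypothyroidism,0.91,0.85,0.98
male,30-39,hypothyroidism,0.94,0.87,1.01
male,40-49,hypothyroidism,1.09,1.02,1.17
male,50-59,hypothyroidism,1.50,1.42,1.59
male,60-69,hypothyroidism,1.96,1.87,2.07
male,70-79,hypothyroidism,1.97,1.87,2.07
male,10-19,hyperthyroidism,0.24,0.21,0.28
male,20-29,hyperthyroidism,0.55,0.50,0.60
male,30-39,hyperthyroidism,0.48,0.43,0.53
male,40-49,hyperthyroidism,0.53,0.48,0.58
male,50-59,hyperthyroidism,0.71,0.65,0.77
male,60-69,hyperthyroidism,0.94,0.87,1.01
male,70-79,hyperthyroidism,0.91,0.84,0.98
female,10-19,hypothyroidism,1.01,0.95,1.09
female,20-29,hypothyroidism,1.95,1.86,2.06
female,30-39,hypothyroidism,2.03,1.93,2.14
female,40-49,hypothyroidism,2.34,2.23,2.46
female,50-59,hypothyroidism,2.35,2.24,2.47
female,60-69,hypothyroidism,2.56,2.44,2.69
female,70-79,hypothyroidism,2.87,2.74,3.01
female,10-19,hyperthyroidism,1.03,0.96,1.10
female,20-29,hyperthyroidism,3.40,3.28,3.54
female,30-39,hyperthyroidism,3.07,2.95,3.20
female,40-49,hyperthyroidism,3.59,3.45,3.74
female,50-59,hyperthyroidism,2.35,2.24,2.47
female,60-69,hyperthyroidism,1.91,1.80,2.02
female,70-79,hyperthyroidism,1.97,1.86,2.08
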