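parameter,sex,age_group,prior_pct
t14,male,10-19,0.027
t14,male,20-29,0.072
t14,male,30-39,0.129
t14,male,40-49,0.192
t14,male,50-59,0.357
t14,male,60-69,0.534
t14,male,70-79,0.807
t14,female,10-19,0.105
t14,female,20-29,0.549
t14,female,30-39,1.017
t14,female,40-49,1.821
t14,female,50-59,2.334
t14,female,60-69,2.718
t14,female,70-79,2.652
t15,male,10-19,0.009
t15,male,20-29,0.018
t15,male,30-39,0.039
t15,male,40-49,0.063
t15,male,50-59,0.054
t15,male,60-69,0.081
t15,male,70-79,0.087
t15,female,10-19,0.042
t15,female,20-29,0.234
t15,female,30-39,0.255
t15,female,40-49,0.270
t15,female,50-59,0.273
t15,female,60-69,0.336
t15,female,70-79,0.387
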