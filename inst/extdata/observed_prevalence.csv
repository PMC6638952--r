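table,sex,age_group,category,observed_pct,reference_predicted_pct
diagnosed,male,20-29,treated,0.97,0.56
diagnosed,male,30-39,treated,1.56,1.71
diagnosed,male,40-49,treated,3.30,3.20
diagnosed,male,50-59,treated,4.42,4.62
diagnosed,male,60-69,treated,7.63,6.45
diagnosed,male,70-79,treated,8.19,8.84
diagnosed,female,20-29,treated,5.04,4.45
diagnosed,female,30-39,treated,7.28,8.33
diagnosed,female,40-49,treated,13.95,13.31
diagnosed,female,50-59,treated,18.07,17.66
diagnosed,female,60-69,treated,25.23,22.20
diagnosed,female,70-79,treated,28.22,25.48
undiagnosed,male,20-29,subclin_hypo,3.26,1.43
undiagnosed,male,30-39,subclin_hypo,3.85,2.53
undiagnosed,male,40-49,subclin_hypo,3.45,2.51
undiagnosed,male,50-59,subclin_hypo,4.43,2.94
undiagnosed,male,60-69,subclin_hypo,5.53,4.19
undiagnosed,male,70-79,subclin_hypo,6.28,5.09
undiagnosed,male,20-29,overt_hypo,0.15,0.03
undiagnosed,male,30-39,overt_hypo,0.15,0.07
undiagnosed,male,40-49,overt_hypo,0.00,0.08
undiagnosed,male,50-59,overt_hypo,0.00,0.09
undiagnosed,male,60-69,overt_hypo,0.00,0.12
undiagnosed,male,70-79,overt_hypo,0.00,0.15
undiagnosed,male,20-29,subclin_hyper,0.15,0.10
undiagnosed,male,30-39,subclin_hyper,0.44,0.16
undiagnosed,male,40-49,subclin_hyper,0.16,0.14
undiagnosed,male,50-59,subclin_hyper,0.00,0.16
undiagnosed,male,60-69,subclin_hyper,0.22,0.22
undiagnosed,male,70-79,subclin_hyper,0.00,0.27
undiagnosed,male,20-29,overt_hyper,0.15,0.03
undiagnosed,male,30-39,overt_hyper,0.00,0.04
undiagnosed,male,40-49,overt_hyper,0.00,0.04
undiagnosed,male,50-59,overt_hyper,0.00,0.04
undiagnosed,male,60-69,overt_hyper,0.22,0.06
undiagnosed,male,70-79,overt_hyper,0.00,0.08
undiagnosed,female,20-29,subclin_hypo,3.38,3.24
undiagnosed,female,30-39,subclin_hypo,5.15,5.32
undiagnosed,female,40-49,subclin_hypo,3.76,5.39
undiagnosed,female,50-59,subclin_hypo,4.37,6.12
undiagnosed,female,60-69,subclin_hypo,2.59,6.14
undiagnosed,female,70-79,subclin_hypo,6.44,6.81
undiagnosed,female,20-29,overt_hypo,0.00,0.06
undiagnosed,female,30-39,overt_hypo,0.17,0.16
undiagnosed,female,40-49,overt_hypo,0.00,0.17
undiagnosed,female,50-59,overt_hypo,0.24,0.19
undiagnosed,female,60-69,overt_hypo,0.29,0.20
undiagnosed,female,70-79,overt_hypo,0.00,0.21
undiagnosed,female,20-29,subclin_hyper,0.19,0.62
undiagnosed,female,30-39,subclin_hyper,0.66,1.05
undiagnosed,female,40-49,subclin_hyper,0.54,0.82
undiagnosed,female,50-59,subclin_hyper,0.00,1.07
undiagnosed,female,60-69,subclin_hyper,0.29,0.61
undiagnosed,female,70-79,subclin_hyper,0.00,0.56
undiagnosed,female,20-29,overt_hyper,0.00,0.21
undiagnosed,female,30-39,overt_hyper,0.50,0.28
undiagnosed,female,40-49,overt_hyper,0.36,0.27
undiagnosed,female,50-59,overt_hyper,0.00,0.30
undiagnosed,female,60-69,overt_hyper,0.00,0.21
undiagnosed,female,70-79,overt_hyper,0.00,0.16
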