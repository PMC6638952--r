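study,transition,sex,n_subjects,years_followup,n_cases,pfu_override,pfu_printed,pa_printed,sd_printed,exclude_pool,reproducible
Diez 2004,t42,b,107,2.6,28,,0.262,0.095,0.028,FALSE,TRUE
Huber 2002,t42,f,82,9.2,23,,0.280,0.036,0.021,FALSE,TRUE
Imaizumi 2011,t42,b,71,4.2,5,,0.070,0.019,0.016,FALSE,TRUE
Park 2013,t42,b,169,5.0,19,,0.112,0.024,0.012,FALSE,TRUE
Rosario 2016,t42,f,252,5.0,48,,0.190,0.042,0.013,FALSE,TRUE
Somwaru 2012,t42,b,369,4.0,18,0.050,0.050,0.013,0.006,FALSE,TRUE
Vanderpump 1995,t42,f,44,20.0,24,0.550,0.550,0.039,0.029,FALSE,TRUE
Diez 2004,t47,b,107,2.6,40,,0.374,0.144,0.034,FALSE,TRUE
Huber 2002,t47,f,82,9.2,3,,,0.004,0.007,TRUE,TRUE
Imaizumi 2011,t47,b,71,4.2,38,,0.535,0.174,0.045,FALSE,TRUE
Park 2013,t47,b,169,5.0,80,,0.473,0.121,0.025,FALSE,TRUE
Rosario 2016,t47,f,252,5.0,57,0.228,0.228,0.050,0.014,FALSE,TRUE
Somwaru 2012,t47,b,369,4.0,92,0.250,0.250,0.070,0.013,FALSE,TRUE
Asvold 2012,t26,b,418,11.1,412,0.990,0.990,0.370,0.024,FALSE,FALSE
Vanderpump 1995,t26,b,79,20.0,51,,0.646,0.050,0.025,FALSE,TRUE
Rosario 2010,t53,f,102,3.4,3,,0.029,0.010,0.010,FALSE,TRUE
Vadiveloo 2011,t53,b,2024,7.0,494,,0.244,0.039,0.004,FALSE,TRUE
Rosario 2010,t57,f,102,3.4,24,0.240,0.240,0.087,0.030,FALSE,TRUE
Vadiveloo 2011,t57,b,2024,7.0,721,0.360,0.360,0.062,0.005,FALSE,TRUE
Asvold 2012,t36,b,120,11.1,112,0.930,0.930,0.230,0.038,FALSE,FALSE
Vanderpump 1995,t36,b,20,20.0,15,,0.759,0.067,0.056,FALSE,TRUE
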