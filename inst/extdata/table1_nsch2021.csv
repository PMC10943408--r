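sex,age_band,fpl,population,pa_days_mean,pa_days_se,overweight_prev,obesity_prev
male,6-10,<100%,1968958,3.97,0.14,18.18,34.29
male,6-10,100-199%,2152037,3.90,0.13,19.97,25.17
male,6-10,200-399%,3019002,4.16,0.09,17.84,29.14
male,6-10,>=400%,3185931,4.39,0.06,18.23,16.05
male,11-13,<100%,1286059,3.26,0.18,18.76,27.71
male,11-13,100-199%,1509539,3.44,0.13,21.97,24.38
male,11-13,200-399%,1788511,3.64,0.10,19.64,18.79
male,11-13,>=400%,1837003,3.91,0.09,15.26,10.26
male,14-17,<100%,1572564,3.20,0.14,12.36,22.12
male,14-17,100-199%,1874065,3.01,0.12,19.18,25.14
male,14-17,200-399%,2532555,3.42,0.08,13.58,20.26
male,14-17,>=400%,2810412,3.70,0.06,13.38,10.77
female,6-10,<100%,1570444,3.68,0.14,21.40,28.30
female,6-10,100-199%,2084059,3.83,0.11,25.48,17.52
female,6-10,200-399%,2889740,3.95,0.08,17.05,18.41
female,6-10,>=400%,3315163,4.11,0.06,14.91,9.24
female,11-13,<100%,1071792,2.80,0.19,24.19,24.13
female,11-13,100-199%,1414506,2.70,0.13,19.95,17.33
female,11-13,200-399%,1892410,3.11,0.10,18.22,13.17
female,11-13,>=400%,1734083,3.38,0.07,13.79,6.64
female,14-17,<100%,1690081,2.64,0.15,15.03,20.59
female,14-17,100-199%,1715986,2.44,0.11,15.49,21.23
female,14-17,200-399%,2439551,2.75,0.08,14.78,12.91
female,14-17,>=400%,2524229,3.01,0.06,12.08,6.31
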