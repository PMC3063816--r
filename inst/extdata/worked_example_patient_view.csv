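class,n_patients,n_admissions,observed_deaths,predicted_deaths
1,164884,164884,8836,6971
2,41876,83752,2868,3363
3,15356,46068,1377,1899
4,7064,28256,727,1153
"5,6",6055,32490,695,1302
7-9,2938,22795,404,820
10-20,2063,26364,265,714
>20,426,13957,55,157
Total,240662,418566,15227,16379
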