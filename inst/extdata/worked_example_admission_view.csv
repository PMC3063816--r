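class,n_admissions,observed_deaths,predicted_deaths
1,240662,8836,9783
2,75778,2868,2981
3,33902,1377,1389
4,18546,727,740
"5,6",19124,695,714
7-9,12634,404,421
10-20,12483,265,293
>20,5437,55,57
Total,418566,15227,16379
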