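participant,pars_triangularis_putamen,pars_triangularis_thalamus,pars_opercularis_putamen,pars_opercularis_thalamus
1,1913,2594,1337,342
2,1539,1730,1148,382
3,2439,3439,2468,2996
4,766,2479,2083,2045
5,841,863,811,901
6,2482,0,1534,0
7,1341,1849,605,0
8,1622,0,870,0
9,1670,1302,2171,170
10,562,1874,379,0
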