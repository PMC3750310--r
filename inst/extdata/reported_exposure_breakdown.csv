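source,exposure_mean,cr_mean,exposure_median,cr_median,exposure_p90,cr_p90,exposure_extreme,cr_extreme
Rice,4.80,37.56,1.80,54.91,6.90,33.54,27.00,28.67
Wheat,0.47,3.65,0.16,4.79,1.40,6.81,2.30,2.44
Coarse cereal,0.04,0.32,0.02,0.61,0.09,0.42,0.29,0.30
Tuber,0.01,0.12,0.00,0.05,0.05,0.24,0.10,0.10
Pork,0.50,3.89,0.03,0.87,0.99,4.81,5.50,5.84
Innard,0.15,1.19,0.00,0.00,0.46,2.26,0.01,0.01
Fatstock except pork,0.01,0.11,0.00,0.05,0.04,0.21,0.09,0.09
Poultry,0.02,0.18,0.01,0.22,0.06,0.28,0.09,0.09
Aquatic product,1.09,8.51,0.10,3.05,2.15,10.45,4.55,4.83
Egg,0.14,1.11,0.06,1.96,0.25,1.22,0.60,0.64
Milk,0.10,0.78,0.04,1.09,0.26,1.28,0.79,0.84
Dry bean,0.24,1.87,0.01,0.36,0.27,1.32,1.43,1.52
Fresh vegetable,5.13,40.21,1.00,30.51,7.50,36.46,51.00,54.15
Fruit,0.06,0.50,0.05,1.53,0.15,0.73,0.45,0.48
Dietary exposure,12.77,100.00,3.28,100.00,20.57,100.00,94.18,100.00
Water exposure,0.03,,0.03,,0.05,,0.05,
Smoking exposure,3.93,,0.00,,16.15,,16.39,
Daily exposure,16.73,,3.31,,36.78,,110.63,
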