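"region","sex","risk_factor","bound","deaths_all_ages","deaths_premature","printed_ratio_pct"
"Andean Latin America","men","bmi","estimate",3299,2659,80.6
"Andean Latin America","men","bmi","lower",1605,1494,93.13
"Andean Latin America","men","bmi","upper",5687,3920,68.92
"Andean Latin America","men","sbp","estimate",13590,6072,44.68
"Andean Latin America","men","sbp","lower",8107,3905,48.16
"Andean Latin America","men","sbp","upper",18597,7854,42.23
"Andean Latin America","men","tc","estimate",3118,1851,59.37
"Andean Latin America","men","tc","lower",562,473,84.25
"Andean Latin America","men","tc","upper",7135,3519,49.33
"Andean Latin America","men","nonhdl","estimate",6841,3886,56.81
"Andean Latin America","men","nonhdl","lower",2548,2003,78.6
"Andean Latin America","men","nonhdl","upper",11916,5631,47.26
"Andean Latin America","women","bmi","estimate",3124,2390,76.52
"Andean Latin America","women","bmi","lower",1602,1474,92.02
"Andean Latin America","women","bmi","upper",5450,3335,61.19
"Andean Latin America","women","sbp","estimate",11216,3466,30.91
"Andean Latin America","women","sbp","lower",5757,1848,32.1
"Andean Latin America","women","sbp","upper",16342,4883,29.88
"Andean Latin America","women","tc","estimate",3532,1580,44.74
"Andean Latin America","women","tc","lower",622,495,79.54
"Andean Latin America","women","tc","upper",8193,2855,34.85
"Andean Latin America","women","nonhdl","estimate",6189,2813,45.45
"Andean Latin America","women","nonhdl","lower",2025,1490,73.56
"Andean Latin America","women","nonhdl","upper",11376,4051,35.61
"Caribbean","men","bmi","estimate",6176,5136,83.16
"Caribbean","men","bmi","lower",2832,2651,93.61
"Caribbean","men","bmi","upper",10630,7880,74.13
"Caribbean","men","sbp","estimate",27503,14327,52.09
"Caribbean","men","sbp","lower",16887,9244,54.74
"Caribbean","men","sbp","upper",36885,18297,49.61
"Caribbean","men","tc","estimate",6178,3828,61.97
"Caribbean","men","tc","lower",1123,930,82.8
"Caribbean","men","tc","upper",13847,7373,53.24
"Caribbean","men","nonhdl","estimate",12863,7824,60.82
"Caribbean","men","nonhdl","lower",5229,4119,78.78
"Caribbean","men","nonhdl","upper",21835,11345,51.96
"Caribbean","women","bmi","estimate",5134,3932,76.59
"Caribbean","women","bmi","lower",2312,2104,90.99
"Caribbean","women","bmi","upper",9475,5920,62.47
"Caribbean","women","sbp","estimate",24135,9617,39.85
"Caribbean","women","sbp","lower",12787,5259,41.12
"Caribbean","women","sbp","upper",34567,13180,38.13
"Caribbean","women","tc","estimate",7710,3697,47.95
"Caribbean","women","tc","lower",1593,1248,78.35
"Caribbean","women","tc","upper",17115,6596,38.54
"Caribbean","women","nonhdl","estimate",13125,6342,48.32
"Caribbean","women","nonhdl","lower",4588,3397,74.04
"Caribbean","women","nonhdl","upper",23590,9102,38.59
"Central Latin America","men","bmi","estimate",21147,17209,81.38
"Central Latin America","men","bmi","lower",11158,10396,93.17
"Central Latin America","men","bmi","upper",34447,24328,70.62
"Central Latin America","men","sbp","estimate",81481,40272,49.42
"Central Latin America","men","sbp","lower",53892,28791,53.42
"Central Latin America","men","sbp","upper",107084,49875,46.58
"Central Latin America","men","tc","estimate",16548,10278,62.11
"Central Latin America","men","tc","lower",3844,3269,85.04
"Central Latin America","men","tc","upper",35438,18462,52.1
"Central Latin America","men","nonhdl","estimate",39095,22925,58.64
"Central Latin America","men","nonhdl","lower",15439,12156,78.74
"Central Latin America","men","nonhdl","upper",65842,32755,49.75
"Central Latin America","women","bmi","estimate",16734,12342,73.75
"Central Latin America","women","bmi","lower",8649,7816,90.36
"Central Latin America","women","bmi","upper",28854,16888,58.53
"Central Latin America","women","sbp","estimate",67962,21806,32.09
"Central Latin America","women","sbp","lower",40603,14077,34.67
"Central Latin America","women","sbp","upper",93829,28469,30.34
"Central Latin America","women","tc","estimate",20079,8553,42.6
"Central Latin America","women","tc","lower",4416,3340,75.62
"Central Latin America","women","tc","upper",43640,14340,32.86
"Central Latin America","women","nonhdl","estimate",35646,15098,42.35
"Central Latin America","women","nonhdl","lower",11593,8294,71.54
"Central Latin America","women","nonhdl","upper",64701,21297,32.92
"Southern and Tropical Latin America","men","bmi","estimate",36418,29324,80.52
"Southern and Tropical Latin America","men","bmi","lower",19372,17847,92.13
"Southern and Tropical Latin America","men","bmi","upper",58019,41325,71.23
"Southern and Tropical Latin America","men","sbp","estimate",155845,83297,53.45
"Southern and Tropical Latin America","men","sbp","lower",121477,69701,57.38
"Southern and Tropical Latin America","men","sbp","upper",187436,94929,50.65
"Southern and Tropical Latin America","men","tc","estimate",30617,19949,65.16
"Southern and Tropical Latin America","men","tc","lower",9504,7806,82.14
"Southern and Tropical Latin America","men","tc","upper",58140,33399,57.45
"Southern and Tropical Latin America","men","nonhdl","estimate",61208,38343,62.64
"Southern and Tropical Latin America","men","nonhdl","lower",25953,20426,78.71
"Southern and Tropical Latin America","men","nonhdl","upper",99449,54830,55.13
"Southern and Tropical Latin America","women","bmi","estimate",27466,19765,71.96
"Southern and Tropical Latin America","women","bmi","lower",13672,12201,89.25
"Southern and Tropical Latin America","women","bmi","upper",48261,27444,56.86
"Southern and Tropical Latin America","women","sbp","estimate",121181,41732,34.44
"Southern and Tropical Latin America","women","sbp","lower",81127,31403,38.71
"Southern and Tropical Latin America","women","sbp","upper",158501,50817,32.06
"Southern and Tropical Latin America","women","tc","estimate",32048,14050,43.84
"Southern and Tropical Latin America","women","tc","lower",7881,5875,74.54
"Southern and Tropical Latin America","women","tc","upper",66512,22882,34.4
"Southern and Tropical Latin America","women","nonhdl","estimate",49151,22272,45.31
"Southern and Tropical Latin America","women","nonhdl","lower",16381,11925,72.8
"Southern and Tropical Latin America","women","nonhdl","upper",89467,31983,35.75
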