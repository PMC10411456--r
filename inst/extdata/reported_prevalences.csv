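group,nutrient,baseline,scenario1,scenario2
12_35,vita_ug,67,52,50
12_35,folate_ug,92,73,73
12_35,vitd_ug,87,47,47
12_35,calcium_mg,77,49,49
12_35,iron_mg,84,58,58
12_35,zinc_mg,76,44,44
36_60,vita_ug,63.7,39.6,40.3
36_60,folate_ug,90.7,68.1,69.0
36_60,vitd_ug,84.1,26.9,32.0
36_60,calcium_mg,76.8,43.4,45.4
36_60,iron_mg,75.8,27.4,28.6
36_60,zinc_mg,76.2,32.7,34.9
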