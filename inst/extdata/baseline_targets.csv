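group,nutrient,prevalence,p25,p50,p75
12_35,vita_ug,67,17.6,123.2,401.2
12_35,folate_ug,92,9.6,26.1,54.7
12_35,vitd_ug,87,0,0.3,2.2
12_35,calcium_mg,77,146.4,242.7,402
12_35,iron_mg,84,1.7,2.8,4.5
12_35,zinc_mg,76,1.3,2.2,3.3
36_60,vita_ug,63.7,23.5,167.5,448.4
36_60,folate_ug,90.7,14.8,33.8,68.2
36_60,vitd_ug,84.1,0,0.5,3.2
36_60,calcium_mg,76.8,182.8,278.8,433.2
36_60,iron_mg,75.8,2.4,3.7,5.9
36_60,zinc_mg,76.2,1.6,2.5,3.9
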