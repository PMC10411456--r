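food_id,name,basis,density_g_per_mL,milk_type,ycm_ageband,energy_kcal,protein_g,vita_ug,vitc_mg,vitd_ug,folate_ug,calcium_mg,iron_mg,zinc_mg
BG_ENERGY,background diet energy (synthetic pseudo-food),per_100_g,NA,none,,100,0,0,0,0,0,0,0,0
BG_PROTEIN,background diet protein (synthetic pseudo-food),per_100_g,NA,none,,0,100,0,0,0,0,0,0,0
BG_VITA,background diet vitamin A (synthetic pseudo-food),per_100_g,NA,none,,0,0,100,0,0,0,0,0,0
BG_VITC,background diet vitamin C (synthetic pseudo-food),per_100_g,NA,none,,0,0,0,100,0,0,0,0,0
BG_VITD,background diet vitamin D (synthetic pseudo-food),per_100_g,NA,none,,0,0,0,0,100,0,0,0,0
BG_FOLATE,background diet folate (synthetic pseudo-food),per_100_g,NA,none,,0,0,0,0,0,100,0,0,0
BG_CALCIUM,background diet calcium (synthetic pseudo-food),per_100_g,NA,none,,0,0,0,0,0,0,100,0,0
BG_IRON,background diet iron (synthetic pseudo-food),per_100_g,NA,none,,0,0,0,0,0,0,0,100,0
BG_ZINC,background diet zinc (synthetic pseudo-food),per_100_g,NA,none,,0,0,0,0,0,0,0,0,100
CONDENSED,sweetened condensed milk as consumed (illustrative),per_100_mL,1.07,condensed,,70,1.7,22,0.5,0.03,3,80,0.07,0.3
YCM1,young-child milk 1+ reconstituted (illustrative),per_100_mL,1.03,ycm,1plus,67,2.2,84,10,2.2,23,151,1.03,0.9
YCM3,young-child milk 3+ reconstituted (illustrative),per_100_mL,1.03,ycm,3plus,75,2.5,105,10,3.0,30,164,1.95,1.3
COW,plain cow's milk (illustrative),per_100_mL,1.03,cow,,61,3.2,28,0,0.03,5,113,0.03,0.4
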