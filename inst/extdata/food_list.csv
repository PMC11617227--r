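food,energy_kcal_g,vitamin_a_ug_g,retinol_ug_g,folate_ug_g,folic_acid_ug_g,vitamin_b12_ug_g,iron_mg_g,zinc_mg_g,phytate_mg_g,vehicle,median_g_ame_day,log_sd
maize_flour,3.6,0,0,0.25,0,0,0.025,0.018,6,none,300,0.6
rice,3.6,0,0,0.08,0,0,0.008,0.012,1.1,none,120,0.7
cassava,1.6,0.01,0,0.27,0,0,0.003,0.003,0.6,none,150,0.8
wheat_flour_products,3.5,0,0,0.3,0,0,0.012,0.008,2,wheat_flour,60,0.9
vegetable_oil,8.8,0,0,0,0,0,0,0,0,oil,25,0.6
legumes,3.4,0,0,1.8,0,0,0.05,0.025,8,none,40,0.8
fish_meat,1.8,0.05,0.05,0.1,0,0.02,0.015,0.015,0,none,50,0.8
leafy_vegetables,0.4,3.0,0,1.2,0,0,0.02,0.003,0.2,none,60,0.8
fruit,0.6,0.3,0,0.2,0,0,0.003,0.001,0.1,none,40,0.9
tomato_onion,0.3,0.4,0,0.25,0,0,0.003,0.002,0.1,none,30,0.8
sugar,4.0,0,0,0,0,0,0,0,0,none,25,0.9
bouillon,2.5,0,0,0,0,0,0,0,0,bouillon,NA,NA
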