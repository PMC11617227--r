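country,vehicle,nutrient,target_level,compliance_fraction,printed_actual,printed_decimals,unit,source
Cameroon,oil,vitamin_a,12,0.75,9,0,mg_per_kg,"national standard; oil assumed 75% of target"
Cameroon,wheat_flour,folic_acid,5,0.33,1.65,2,mg_per_kg,"national standard; wheat flour assumed 33% of target"
Cameroon,wheat_flour,vitamin_b12,0.04,0.33,0.013,3,mg_per_kg,"national standard; wheat flour assumed 33% of target"
Cameroon,wheat_flour,iron,60,0.33,19.8,1,mg_per_kg,"national standard; wheat flour assumed 33% of target"
Cameroon,wheat_flour,zinc,95,0.33,31.35,2,mg_per_kg,"national standard; wheat flour assumed 33% of target"
Haiti,oil,vitamin_a,15.02,0.80,12.02,2,mg_per_kg,"national standard; oil assumed 80% of target"
Haiti,wheat_flour,folic_acid,1.5,0.38,0.57,2,mg_per_kg,"national standard; wheat flour assumed 38% of target"
Haiti,wheat_flour,iron,30,0.38,11.4,1,mg_per_kg,"national standard; wheat flour assumed 38% of target"
Haiti,wheat_flour,zinc,60,0.38,22.8,1,mg_per_kg,"national standard; wheat flour assumed 38% of target"
Ghana,oil,vitamin_a,10.0,1.06,10.6,1,mg_per_kg,"national standard; oil assumed 106% of target"
Ghana,wheat_flour,vitamin_a,2.0,0.39,0.8,1,mg_per_kg,"national standard; wheat flour assumed 39% of target"
Ghana,wheat_flour,folic_acid,2.08,0.39,0.81,2,mg_per_kg,"national standard; wheat flour assumed 39% of target"
Ghana,wheat_flour,vitamin_b12,0.01,0.39,0.004,3,mg_per_kg,"national standard; wheat flour assumed 39% of target"
Ghana,wheat_flour,iron,58.5,0.39,22.8,1,mg_per_kg,"national standard; wheat flour assumed 39% of target"
Ghana,wheat_flour,zinc,28.3,0.39,11.0,1,mg_per_kg,"national standard; wheat flour assumed 39% of target"
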