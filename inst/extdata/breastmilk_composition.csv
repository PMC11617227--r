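nutrient,amount_per_g,unit,source
vitamin_a,0.5,ug_rae,"mature human milk, well-nourished reference"
retinol,0.5,ug,"mature human milk, well-nourished reference"
folate,0.085,ug_dfe,"mature human milk"
folic_acid,0,ug,"human milk contains no synthetic folic acid"
vitamin_b12,0.00097,ug,"mature human milk"
iron,0.0003,mg,"mature human milk"
zinc,0.0012,mg,"mature human milk"
phytate,0,mg,"human milk"
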