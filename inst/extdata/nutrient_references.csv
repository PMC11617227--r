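nutrient,group_id,ear,ear_unit,ear_basis,ul,ul_basis,source
vitamin_a,child_6_11,400,ug_rae,total,600,preformed_retinol,"IOM 2001 (EAR not defined 7-12 mo; AI-derived value)"
vitamin_a,child_12_47,210,ug_rae,total,600,preformed_retinol,"IOM 2001, 1-3 y"
vitamin_a,child_48_59,275,ug_rae,total,900,preformed_retinol,"IOM 2001, 4-8 y"
vitamin_a,wra_15_17,485,ug_rae,total,2800,preformed_retinol,"IOM 2001, females 14-18 y"
vitamin_a,wra_18_29,500,ug_rae,total,3000,preformed_retinol,"IOM 2001, females 19-50 y"
vitamin_a,wra_30_49,500,ug_rae,total,3000,preformed_retinol,"IOM 2001, females 19-50 y"
vitamin_a,men_18_29,625,ug_rae,total,3000,preformed_retinol,"IOM 2001, males 19+ y"
vitamin_a,men_30_59,625,ug_rae,total,3000,preformed_retinol,"IOM 2001, males 19+ y"
vitamin_a,men_60p,625,ug_rae,total,3000,preformed_retinol,"IOM 2001, males 19+ y"
folate,child_6_11,65,ug_dfe,total,300,folic_acid,"IOM 1998 (EAR not defined 7-12 mo; AI-derived value; UL extended from 1-3 y)"
folate,child_12_47,120,ug_dfe,total,300,folic_acid,"IOM 1998, 1-3 y"
folate,child_48_59,160,ug_dfe,total,400,folic_acid,"IOM 1998, 4-8 y"
folate,wra_15_17,330,ug_dfe,total,800,folic_acid,"IOM 1998, females 14-18 y"
folate,wra_18_29,320,ug_dfe,total,1000,folic_acid,"IOM 1998, adults"
folate,wra_30_49,320,ug_dfe,total,1000,folic_acid,"IOM 1998, adults"
folate,men_18_29,320,ug_dfe,total,1000,folic_acid,"IOM 1998, adults"
folate,men_30_59,320,ug_dfe,total,1000,folic_acid,"IOM 1998, adults"
folate,men_60p,320,ug_dfe,total,1000,folic_acid,"IOM 1998, adults"
vitamin_b12,child_6_11,0.4,ug,total,NA,none,"IOM 1998 (EAR not defined 7-12 mo; AI-derived value); no UL defined"
vitamin_b12,child_12_47,0.7,ug,total,NA,none,"IOM 1998, 1-3 y; no UL defined"
vitamin_b12,child_48_59,1.0,ug,total,NA,none,"IOM 1998, 4-8 y; no UL defined"
vitamin_b12,wra_15_17,2.0,ug,total,NA,none,"IOM 1998, females 14-18 y; no UL defined"
vitamin_b12,wra_18_29,2.0,ug,total,NA,none,"IOM 1998, adults; no UL defined"
vitamin_b12,wra_30_49,2.0,ug,total,NA,none,"IOM 1998, adults; no UL defined"
vitamin_b12,men_18_29,2.0,ug,total,NA,none,"IOM 1998, adults; no UL defined"
vitamin_b12,men_30_59,2.0,ug,total,NA,none,"IOM 1998, adults; no UL defined"
vitamin_b12,men_60p,2.0,ug,total,NA,none,"IOM 1998, adults; no UL defined"
iron,child_6_11,6.9,mg,total,40,total_intake,"IOM 2001, 7-12 mo; UL 40 mg/d children"
iron,child_12_47,3.0,mg,total,40,total_intake,"IOM 2001, 1-3 y; UL 40 mg/d children"
iron,child_48_59,4.1,mg,total,40,total_intake,"IOM 2001, 4-8 y; UL 40 mg/d children"
iron,wra_15_17,7.9,mg,total,45,total_intake,"IOM 2001, females 14-18 y; UL 45 mg/d"
iron,wra_18_29,8.1,mg,total,45,total_intake,"IOM 2001, females 19-50 y; UL 45 mg/d"
iron,wra_30_49,8.1,mg,total,45,total_intake,"IOM 2001, females 19-50 y; UL 45 mg/d"
iron,men_18_29,6.0,mg,total,45,total_intake,"IOM 2001, males 19+ y; UL 45 mg/d"
iron,men_30_59,6.0,mg,total,45,total_intake,"IOM 2001, males 19+ y; UL 45 mg/d"
iron,men_60p,6.0,mg,total,45,total_intake,"IOM 2001, males 19+ y; UL 45 mg/d"
zinc,child_6_11,0.80,mg,absorbed,5,total_intake,"EFSA 2014 physiological requirement; IOM 2001 UL"
zinc,child_12_47,0.86,mg,absorbed,7,total_intake,"EFSA 2014 physiological requirement; IOM 2001 UL"
zinc,child_48_59,1.00,mg,absorbed,12,total_intake,"EFSA 2014 physiological requirement; IOM 2001 UL"
zinc,wra_15_17,1.85,mg,absorbed,34,total_intake,"IZiNCG corrected physiological requirement; IOM 2001 UL"
zinc,wra_18_29,1.86,mg,absorbed,40,total_intake,"IZiNCG corrected physiological requirement; IOM 2001 UL"
zinc,wra_30_49,1.86,mg,absorbed,40,total_intake,"IZiNCG corrected physiological requirement; IOM 2001 UL"
zinc,men_18_29,2.69,mg,absorbed,40,total_intake,"IZiNCG corrected physiological requirement; IOM 2001 UL"
zinc,men_30_59,2.69,mg,absorbed,40,total_intake,"IZiNCG corrected physiological requirement; IOM 2001 UL"
zinc,men_60p,2.69,mg,absorbed,40,total_intake,"IZiNCG corrected physiological requirement; IOM 2001 UL"
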