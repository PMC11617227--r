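model,parameter,value,source
armah,intercept,6.294,"Armah et al. 2013 J Nutr 143:1136, total-diet nonheme iron absorption"
armah,b_ln_ferritin,-0.709,"Armah et al. 2013"
armah,b_ln_vitc,0.119,"Armah et al. 2013"
armah,b_ln_mfp,0.006,"Armah et al. 2013"
armah,b_ln_tea,-0.055,"Armah et al. 2013"
armah,b_ln_phytate,-0.247,"Armah et al. 2013"
armah,b_ln_calcium,-0.137,"Armah et al. 2013"
armah,b_ln_nonheme,-0.083,"Armah et al. 2013"
armah,ref_vitc_mg,25,"reference value for non-modeled covariate"
armah,ref_mfp_g,50,"reference value for non-modeled covariate"
armah,ref_tea_cups,0,"reference value for non-modeled covariate"
armah,ref_calcium_mg,400,"reference value for non-modeled covariate"
heme,heme_fraction,0.10,"assumed share of total iron consumed as heme iron"
heme,heme_absorption,0.25,"assumed absorption of heme iron"
hces_iron,flat_absorption,0.10,"flat total-diet iron absorption for household-survey mode"
bouillon_iron,default_absorption,0.02,"ferric pyrophosphate in bouillon, primary assumption"
miller_adult,amax_mmol,0.091,"Miller et al. 2007 trivariate saturable zinc absorption model"
miller_adult,kr_mmol,0.033,"Miller et al. 2007"
miller_adult,kp_mmol,0.68,"Miller et al. 2007"
miller_child,amax_mmol,0.048,"Miller-type model, maximal absorption down-scaled for preschool children (approximation)"
miller_child,kr_mmol,0.033,"Miller et al. 2007"
miller_child,kp_mmol,0.68,"Miller et al. 2007"
doets_modified,amax_ug,1.5,"saturable active B12 transport, calibrated to ~50% absorption at 1 ug/d"
doets_modified,k_ug,2.0,"half-saturation dose of active transport"
doets_modified,passive_fraction,0.009,"passive diffusion share of dose"
b12_requirement,absorbed_fraction_of_ear,0.5,"IOM EAR assumes 50% absorption; absorbed-scale requirement = EAR x 0.5"
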