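group_id,median_absorbed_mg,log_sd,source
child_6_11,0.72,0.30,"log-normal approximation to FAO/WHO absorbed-iron requirement tables"
child_12_47,0.50,0.30,"log-normal approximation to FAO/WHO absorbed-iron requirement tables"
child_48_59,0.58,0.30,"log-normal approximation to FAO/WHO absorbed-iron requirement tables"
wra_15_17,1.31,0.50,"log-normal approximation, menstruating adolescents (right-skewed losses)"
wra_18_29,1.46,0.50,"log-normal approximation, menstruating women (right-skewed losses)"
wra_30_49,1.46,0.50,"log-normal approximation, menstruating women (right-skewed losses)"
men_18_29,1.05,0.20,"log-normal approximation, adult men"
men_30_59,1.05,0.20,"log-normal approximation, adult men"
men_60p,0.95,0.20,"log-normal approximation, older men"
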