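group_id,kcal_per_day,source
child_6_11,700,"FAO/WHO/UNU 2004, moderate PA"
child_12_47,1100,"FAO/WHO/UNU 2004, moderate PA"
child_48_59,1400,"FAO/WHO/UNU 2004, moderate PA"
wra_15_17,2400,"FAO/WHO/UNU 2004, moderate PA, nonpregnant nonlactating"
wra_18_29,2400,"FAO/WHO/UNU 2004, moderate PA, nonpregnant nonlactating"
wra_30_49,2350,"FAO/WHO/UNU 2004, moderate PA, nonpregnant nonlactating"
men_18_29,2900,"FAO/WHO/UNU 2004, 65 kg reference male, moderate PA"
men_30_59,2900,"FAO/WHO/UNU 2004, moderate PA"
men_60p,2450,"FAO/WHO/UNU 2004, moderate PA"
inf_0_5,550,"FAO/WHO/UNU 2004"
child_5_9,1650,"FAO/WHO/UNU 2004, moderate PA"
adol_f_10_14,2050,"FAO/WHO/UNU 2004, moderate PA"
adol_m_10_14,2300,"FAO/WHO/UNU 2004, moderate PA"
adol_m_15_17,2800,"FAO/WHO/UNU 2004, moderate PA"
f_50p,2100,"FAO/WHO/UNU 2004, moderate PA"
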