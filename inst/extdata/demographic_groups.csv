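group_id,target_group,sex,age_low_months,age_high_months,physiological_status
child_6_11,child_6_59,any,6,12,none
child_12_47,child_6_59,any,12,48,none
child_48_59,child_6_59,any,48,60,none
wra_15_17,wra,female,180,216,none
wra_18_29,wra,female,216,360,none
wra_30_49,wra,female,360,600,none
men_18_29,men,male,216,360,none
men_30_59,men,male,360,720,none
men_60p,men,male,720,1440,none
inf_0_5,none,any,0,6,none
child_5_9,none,any,60,120,none
adol_f_10_14,none,female,120,180,none
adol_m_10_14,none,male,120,180,none
adol_m_15_17,none,male,180,216,none
f_50p,none,female,600,1440,none
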