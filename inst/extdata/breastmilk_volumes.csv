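age_low_months,age_high_months,milk_g_day,source
6,9,674,"mean breast-milk intake, low- and middle-income settings"
9,12,616,"mean breast-milk intake, low- and middle-income settings"
12,24,529,"mean breast-milk intake, low- and middle-income settings"
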