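# Sex-specific maturity-offset regression coefficients (interaction-term
# anthropometric form). Transcribed 2026-10-01 from the published
# maturity-offset prediction equations for boys and girls; values are used
# verbatim, never re-fitted. Terms: intercept; leg length x sitting height
# (ll_sh); age x leg length (age_ll); age x sitting height (age_sh);
# age x weight (age_wt, female equation only); weight/height x 100 (wt_ht).
sex,intercept,ll_sh,age_ll,age_sh,age_wt,wt_ht
male,-9.236,0.0002708,-0.001663,0.007216,0,0.02292
female,-9.376,0.0001882,0.0022,0.005841,-0.002658,0.07693
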