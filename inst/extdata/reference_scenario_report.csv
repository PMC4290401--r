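ethnicity,age_group,reduction_mg,reduction_se,current_mg,current_se,post_mg,post_se,pct_reduction,pct_se
Mexican American,19-50,250,14,3558,68,3309,59,6.8,0.3
Mexican American,51+,196,12,2898,86,2702,78,6.8,0.4
Other Hispanic,19-50,252,11,3599,45,3347,39,6.9,0.3
Other Hispanic,51+,185,11,2916,68,2731,63,6.3,0.3
Non-Hispanic White,19-50,323,8,3903,55,3581,53,8.3,0.2
Non-Hispanic White,51+,242,5,3320,49,3078,47,7.3,0.2
Non-Hispanic Black,19-50,296,10,3544,66,3248,60,8.4,0.2
Non-Hispanic Black,51+,222,9,3046,74,2824,67,7.2,0.2
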