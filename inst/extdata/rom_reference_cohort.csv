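subject,group,surface_area,cv_pct,max_flexion,max_abduction,max_extension,max_horizontal_abduction,emg_ant_mean_pct_mvc,emg_mid_mean_pct_mvc,emg_post_mean_pct_mvc
h1,h,27732,4.2,150,153,65,213,72,68,49
h2,h,26590,3.9,140,131,42,200,45,51,28
h3,h,26844,3.2,146,137,57,190,52,53,31
h4,h,27122,5,162,160,55,190,74,43,34
h5,h,28002,8.3,150,124,60,205,71,61,49
h6,h,27458,5.3,148,142,51,203,49,63,29
i1,i,13571,3,86,64,NA,NA,35,30,15
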