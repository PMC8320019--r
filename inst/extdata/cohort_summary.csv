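variable,group,mean,dispersion,n
n_male,I/II,7,NA,7
n_male,III/IV,4,NA,7
age_years,I/II,61.86,3.37,7
age_years,III/IV,58.29,3.84,7
s_cr_mg_dl,I/II,1.69,0.35,7
s_cr_mg_dl,III/IV,3.44,1.07,7
egfr_ml_min_173m2,I/II,41.57,6.67,7
egfr_ml_min_173m2,III/IV,27.33,8.51,7
proteinuria_g_day,I/II,0.96,0.31,7
proteinuria_g_day,III/IV,2.11,0.35,7
hematuria_score,I/II,0.33,0.21,7
hematuria_score,III/IV,0.64,0.28,7
podocyte_density_per_1e6um3,I/II,226,NA,7
podocyte_density_per_1e6um3,III/IV,124.5,NA,7
volume_per_podocyte_1e3um3,I/II,4.5,NA,7
volume_per_podocyte_1e3um3,III/IV,8.96,NA,7
podocytes_per_tuft,I/II,137,19,7
podocytes_per_tuft,III/IV,85,17,7
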