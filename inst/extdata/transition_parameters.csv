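"name","kind","lambda","k","value","range_low","range_high","time_unit","source"
"os_irchop","weibull",0.016,0.493,,,,"years","Wilson 2021"
"ae_irchop","point",,,0.642,,,,"Younes 2019"
"efs_irchop","weibull",0.181,1.35,,,,"years","Wilson 2021"
"os_rchop","weibull",0.081,0.769,,,,"years","Wilson 2021"
"ae_rchop","point",,,0.303,,,,"Wilson 2021"
"efs_rchop","weibull",0.187,0.884,,,,"years","Wilson 2021"
"df_to_persistent","point",,,0.35,0.2,0.5,,"Crump 2017"
"os_gdp","weibull",0.0638,0.708,,,,"years","Crump 2014"
"salvage_response","point",,,0.3755,0.3,0.451,,"Crump 2014/2017"
"pfs_gdp","weibull",0.152,0.603,,,,"years","Crump 2014"
"sct_to_cart","point",,,0.201,,,,"Di Blasi 2021"
"sct_to_disease_free","point",,,0.419,,,,"Crump 2017"
"sct_to_relapse","point",,,0.5,,,,"Crump 2017"
"relapse_to_palliation","point",,,0.393,,,,"Crump 2017"
"os_cart","weibull",0.056,0.88,,,,"years","Sermer 2020"
"pd_cart","weibull",0.169,0.658,,,,"years","Sermer 2020"
"cart_df_death","point",,,0.059,,,,"Tomas 2021"
"cart_df_relapse","weibull",0.15,0.876,,,,"years","Di Blasi 2021"
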