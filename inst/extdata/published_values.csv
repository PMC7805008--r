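key,value
deaths_air_millions,1.67
deaths_ambient_pm_millions,0.98
deaths_household_millions,0.61
deaths_ozone_millions,0.17
total_deaths_millions,9.39
daly_household_millions,20.9
total_daly_millions,467.8
mortality_loss_musd,28799
morbidity_loss_musd,8005
total_loss_musd,36804
pct_gdp_total,1.36
per_capita_usd,26.5
healthcare_total_busd,103.7
daly_share_air_fraction,0.115
pm25_state_min,15.8
pm25_state_max,217.6
pct_gdp_state_min,0.67
pct_gdp_state_max,2.15
per_capita_state_min,11.5
per_capita_state_max,62.0
daly_share_copd_pct,22.7
daly_share_lri_pct,15.5
daly_share_lung_cancer_pct,1.3
correlation_r_household,-0.71
printed_deaths_share_air_pct,17.8
printed_deaths_share_ambient_pm_pct,10.4
printed_deaths_share_household_pct,6.5
printed_deaths_share_ozone_pct,1.8
printed_daly_share_household_pct,4.5
printed_lung_group_daly_share_pct,39.5
printed_pm25_extremes_ratio,13.8
printed_pct_gdp_extremes_ratio,3.2
printed_per_capita_extremes_ratio,5.4
printed_healthcare_air_busd,11.9
printed_correlation_r2_household,0.50
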