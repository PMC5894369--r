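country,income_class,male_population_m,poverty_headcount_m,coverage_fraction,public_cost_share,smoking_prevalence_15_74,sticks_per_day,smokers_table1_m,smokers_total_printed_m,price_per_pack,tax_share,gini,mean_income,frp_subset
India,lower-middle,679,268,0.14,0.40,0.10,4,46,46.1,9.2,0.431,0.35,5000,TRUE
Indonesia,lower-middle,130,21,0.55,0.70,0.58,12,53,52.9,5.2,0.574,0.39,9500,TRUE
Bangladesh,lower-middle,81,28,0.26,0.36,0.28,8,25,16.2,3.4,0.770,0.32,3100,TRUE
Philippines,lower-middle,51,13,0.88,0.41,0.39,9,16,13.2,2.3,0.626,0.40,7000,TRUE
Vietnam,lower-middle,46,3,0.60,0.60,0.46,11,15,14.6,2.6,0.357,0.35,5500,TRUE
Armenia,lower-middle,1,0,0.28,1.00,0.53,24,1,0.6,3.1,0.350,0.32,8000,FALSE
China,upper-middle,709,25,0.97,0.26,0.52,14,291,290.9,2.8,0.508,0.46,13000,TRUE
Mexico,upper-middle,63,4,0.89,0.82,0.21,10,10,9.5,5.7,0.670,0.48,17000,TRUE
Turkey,upper-middle,39,0.3,0.85,0.98,0.39,18,12,11.6,10.3,0.821,0.41,23000,FALSE
Brazil,upper-middle,102,8,1.00,0.81,0.23,11,16,15.9,3.2,0.679,0.53,14500,FALSE
Colombia,upper-middle,24,3,0.91,1.00,0.18,8,3,3.1,2.2,0.495,0.51,12500,FALSE
Thailand,upper-middle,34,0.03,0.98,0.99,0.45,9,12,12.0,7.1,0.735,0.36,15000,FALSE
Chile,upper-middle,9,1,0.90,0.90,0.48,13,3,3.2,5.8,0.649,0.47,21000,FALSE
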