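variable,level,sex,elasticity,ci_k,contribution,pct
age_group,30-59,men,0.490,0.053,0.026,7.7
age_group,60+,men,0.164,0.003,0.001,0.1
marital_status,married_cohabiting,men,0.475,-0.012,-0.005,-1.6
marital_status,separated_widowed,men,0.050,-0.032,-0.002,-0.5
education,primary,men,0.059,-0.336,-0.020,-5.8
education,secondary,men,0.183,-0.160,-0.029,-8.6
education,higher,men,0.221,0.533,0.118,34.4
wealth_quintile,poorer,men,0.090,-0.354,-0.032,-9.3
wealth_quintile,middle,men,0.139,0.003,0.000,0.1
wealth_quintile,richer,men,0.177,0.335,0.059,17.4
wealth_quintile,richest,men,0.205,0.621,0.127,37.2
region,mountain,men,-0.008,-0.320,0.003,0.8
region,coast,men,0.058,0.040,0.002,0.7
region,lima,men,0.039,0.496,0.020,5.7
area,urban,men,0.134,0.562,0.075,22.0
altitude,500-1499,men,-0.002,-0.072,0.000,0.0
altitude,1500-2999,men,-0.008,-0.099,0.001,0.2
altitude,3000+,men,-0.026,-0.238,0.006,1.8
chronic_disease,yes,men,0.145,0.087,0.013,3.7
smoker,yes,men,0.011,0.029,0.000,0.1
(residual),(residual),men,NA,NA,-0.021,NA
(total_eci),(total_eci),men,NA,NA,0.342,NA
age_group,30-59,women,0.308,0.056,0.017,20.9
age_group,60+,women,0.067,0.021,0.001,1.7
marital_status,married_cohabiting,women,0.314,-0.078,-0.024,-29.8
marital_status,separated_widowed,women,0.087,-0.009,-0.001,-1.0
education,primary,women,0.069,-0.307,-0.021,-26.0
education,secondary,women,0.115,-0.049,-0.006,-6.8
education,higher,women,0.067,0.506,0.034,41.4
wealth_quintile,poorer,women,0.055,-0.349,-0.019,-23.4
wealth_quintile,middle,women,0.048,-0.014,-0.001,-0.8
wealth_quintile,richer,women,0.049,0.312,0.015,18.7
wealth_quintile,richest,women,0.058,0.651,0.037,45.6
region,mountain,women,0.020,-0.362,-0.007,-8.7
region,coast,women,0.040,0.044,0.002,2.1
region,lima,women,0.019,0.518,0.010,12.1
area,urban,women,0.086,0.552,0.047,57.5
altitude,500-1499,women,0.000,-0.061,0.000,0.0
altitude,1500-2999,women,-0.006,-0.098,0.001,0.7
altitude,3000+,women,-0.028,-0.281,0.008,9.7
chronic_disease,yes,women,0.062,0.050,0.003,3.7
smoker,yes,women,0.003,0.061,0.000,0.2
(residual),(residual),women,NA,NA,-0.280,NA
(total_eci),(total_eci),women,NA,NA,0.082,NA
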