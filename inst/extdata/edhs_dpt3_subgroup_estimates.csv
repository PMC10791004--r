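# Disaggregated DPT3 immunization coverage (%, with 95% CI bounds and
# population shares), children aged 12-23 months, Ethiopian Demographic and
# Health Surveys 2000-2019, as published via the WHO Health Equity Monitor.
# Transcription notes: obvious typographical artifacts in the published
# table (stray/missing parentheses and a comma used as a decimal point)
# were repaired without changing any printed numeral; the Tigray 2016
# population share is blank in the source and is imputed here as 0.075 so
# that the 2016 regional shares sum to 1.000 (Tigray's share is 0.055-0.075
# in the other four rounds). The 2019 wealth-quintile shares are kept
# exactly as published (Q5 0.253 exceeding Q4 0.155), a flagged anomaly.
dimension,subgroup,year,estimate,ci_low,ci_high,population_share
wealth_quintile,Q1,2000,15.3,11.7,19.7,0.213
wealth_quintile,Q2,2000,11.9,8.2,16.9,0.207
wealth_quintile,Q3,2000,15.4,11.8,19.9,0.216
wealth_quintile,Q4,2000,24.9,18.9,32.2,0.195
wealth_quintile,Q5,2000,43.1,34.4,52.2,0.166
wealth_quintile,Q1,2005,25.6,19,33.6,0.24
wealth_quintile,Q2,2005,27.3,21.7,33.8,0.212
wealth_quintile,Q3,2005,33.7,27.5,40.7,0.203
wealth_quintile,Q4,2005,32.5,25.2,40.9,0.184
wealth_quintile,Q5,2005,49.2,41.8,71.8,0.161
wealth_quintile,Q1,2011,26,20.2,32.9,0.229
wealth_quintile,Q2,2011,29.4,23,36.6,0.217
wealth_quintile,Q3,2011,31.4,24.4,39.4,0.204
wealth_quintile,Q4,2011,42.8,35.2,50.8,0.191
wealth_quintile,Q5,2011,63.6,54.5,71.8,0.159
wealth_quintile,Q1,2016,36.4,29.5,44,0.252
wealth_quintile,Q2,2016,50.4,42.6,58.2,0.198
wealth_quintile,Q3,2016,51.4,43.5,59.2,0.224
wealth_quintile,Q4,2016,63.2,55.6,70.2,0.183
wealth_quintile,Q5,2016,76.3,65.5,84.5,0.144
wealth_quintile,Q1,2019,47.7,36.6,59,0.211
wealth_quintile,Q2,2019,59.5,46.3,71.4,0.208
wealth_quintile,Q3,2019,52.1,41.3,62.8,0.174
wealth_quintile,Q4,2019,63.7,48.8,76.4,0.155
wealth_quintile,Q5,2019,83.4,58,94.8,0.253
maternal_education,none,2000,16.3,13.3,19.2,0.796
maternal_education,primary,2000,35,28.5,42.1,0.149
maternal_education,secondary+,2000,53.9,38.7,68.4,0.055
maternal_education,none,2005,28.5,24.5,32.9,0.776
maternal_education,primary,2005,42,34.3,50,0.175
maternal_education,secondary+,2005,65.6,54.5,75.3,0.049
maternal_education,none,2011,31.7,27.5,36.2,0.677
maternal_education,primary,2011,43.5,37.5,49.7,0.27
maternal_education,secondary+,2011,72.8,59.5,83,0.053
maternal_education,none,2016,45.3,40.6,50.2,0.627
maternal_education,primary,2016,62.3,55.7,68.5,0.288
maternal_education,secondary+,2016,79.8,65.6,89.1,0.085
maternal_education,none,2019,55.8,49.4,62.1,0.452
maternal_education,primary,2019,65.1,54.7,74.2,0.406
maternal_education,secondary+,2019,75.6,57.5,87.7,0.142
residence,rural,2000,17.6,15.2,20.3,0.895
residence,urban,2000,51.4,38.8,63.7,0.105
residence,rural,2005,29.8,26.1,33.8,0.921
residence,urban,2005,66.8,57.3,75.1,0.079
residence,rural,2011,32.9,29,37.1,0.858
residence,urban,2011,62,52,71,0.142
residence,rural,2016,49.7,45.3,54.2,0.884
residence,urban,2016,79.5,66.1,88.5,0.116
residence,rural,2019,56.1,49.6,62.3,0.695
residence,urban,2019,76.9,57.4,89.1,0.305
sex,female,2000,19.4,16.1,23.2,0.483
sex,male,2000,22.8,19.4,26.5,0.517
sex,female,2005,30.4,26,35.2,0.489
sex,male,2005,34.9,30.3,39.7,0.511
sex,female,2011,39.3,34.4,44.4,0.477
sex,male,2011,35,30.4,39.9,0.523
sex,female,2016,53.3,48.1,58.5,0.538
sex,male,2016,52.9,47.6,58.2,0.462
sex,female,2019,60.1,51.6,68,0.518
sex,male,2019,64.9,57.4,71.8,0.482
region,Addis Ababa,2000,80.9,66.6,89.9,0.015
region,Afar,2000,1.1,0.1,7.3,0.009
region,Amhara,2000,20.6,15.3,27.2,0.263
region,Benishangul Gumuz,2000,16.7,10.2,26.1,0.009
region,Dire Dawa,2000,52.4,40.8,63.8,0.003
region,Gambella,2000,12.7,6.6,23.6,0.002
region,Harari,2000,50.7,42.4,58.9,0.002
region,Oromia,2000,16.6,12.9,21.2,0.422
region,SNNPR,2000,16.9,13.2,21.5,0.206
region,Somali,2000,24.4,12.3,42.8,0.011
region,Tigray,2000,56.8,47.8,65.5,0.055
region,Addis Ababa,2005,83.8,71,91.6,0.017
region,Afar,2005,4.6,1.8,11.2,0.01
region,Amhara,2005,32.1,25.4,39.7,0.257
region,Benishangul Gumuz,2005,30.7,19.2,45.1,0.009
region,Dire Dawa,2005,62.5,50.4,73.3,0.004
region,Gambella,2005,20.3,11.9,32.3,0.003
region,Harari,2005,45.8,36.7,55.2,0.002
region,Oromia,2005,28.8,22.1,36.6,0.368
region,SNNPR,2005,35.6,28.8,43,0.217
region,Somali,2005,5.6,1.4,20.2,0.042
region,Tigray,2005,52.1,44.3,59.7,0.072
region,Addis Ababa,2011,89.2,78.8,94.8,0.022
region,Afar,2011,11.6,6.8,18.9,0.009
region,Amhara,2011,39.4,31.8,47.7,0.231
region,Benishangul Gumuz,2011,42.9,32.7,53.6,0.012
region,Dire Dawa,2011,76.1,67.5,82.9,0.004
region,Gambella,2011,29.4,20.7,39.9,0.004
region,Harari,2011,54.4,42.7,65.6,0.003
region,Oromia,2011,27.1,21.5,33.6,0.42
region,SNNPR,2011,38.5,30.8,46.8,0.202
region,Somali,2011,25.8,15.9,39,0.026
region,Tigray,2011,74.3,66.1,81,0.067
region,Addis Ababa,2016,95.7,88.9,98,0.026
region,Afar,2016,20.1,11.6,32.5,0.01
region,Amhara,2016,63.8,53.5,72.9,0.182
region,Benishangul Gumuz,2016,76.2,63.8,85.3,0.01
region,Dire Dawa,2016,84.9,75.3,91.2,0.005
region,Gambella,2016,54.8,42.1,67,0.003
region,Harari,2016,58.7,47.2,69.3,0.002
region,Oromia,2016,39.9,33.1,47.1,0.44
region,SNNPR,2016,59,50.7,66.9,0.209
region,Somali,2016,36.3,26.6,47.2,0.038
region,Tigray,2016,81.4,71.1,88.2,0.075
region,Addis Ababa,2019,93.1,84.3,97.2,0.033
region,Afar,2019,27,17.4,39.3,0.015
region,Amhara,2019,82.2,70.8,89.9,0.212
region,Benishangul Gumuz,2019,80.5,70.7,87.7,0.01
region,Dire Dawa,2019,74.5,62.7,83.6,0.006
region,Gambella,2019,69,54.6,80.4,0.004
region,Harari,2019,54.9,41.4,67.8,0.002
region,Oromia,2019,53.6,40.9,65.8,0.394
region,SNNPR,2019,56.3,41.6,70,0.194
region,Somali,2019,26.2,15.1,41.5,0.054
region,Tigray,2019,84.4,72.3,91.8,0.075
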