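# National DPT3 immunization coverage among children aged 12-23 months,
# Ethiopian Demographic and Health Surveys 2000-2019, as published via the
# WHO Health Equity Monitor. n = children sampled for the indicator.
year,estimate,n
2000,21,9543
2005,33,8974
2011,37,10795
2016,53,5980
2019,62,3208
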