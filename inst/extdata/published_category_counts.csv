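vendor,model_type,version_label,release_year,n_positive,n_negative,n_equivocal,n_ood,expected_total
Leadscope,statistical,V2,2010,502,2312,308,245,3367
Leadscope,statistical,V3,2013,505,2413,287,162,3367
Leadscope,statistical,V4,2018,666,2225,407,69,3367
Leadscope,rule_based,V1,2014,1031,2216,41,79,3367
Leadscope,rule_based,V2,2015,1000,2222,89,56,3367
Leadscope,rule_based,V3,2016,927,2264,119,57,3367
Leadscope,rule_based,V4,2017,718,2246,347,56,3367
Leadscope,rule_based,V5,2018,715,2314,283,55,3367
Leadscope,consensus,V1,2014,1811,1894,213,79,3367
Leadscope,consensus,V2,2015,1164,1891,256,56,3367
Leadscope,consensus,V3,2016,1095,1930,285,57,3367
Leadscope,consensus,V4,2017,962,1911,438,56,3367
Leadscope,consensus,V5,2018,923,1975,400,69,3367
MultiCASE,statistical,V1450,2012,985,1888,319,175,3367
MultiCASE,statistical,V1460,2013,985,1888,319,175,3367
MultiCASE,statistical,V1520,2014,683,1961,530,193,3367
MultiCASE,statistical,V1603,2015,683,1963,530,191,3367
MultiCASE,statistical,V1623,2017,683,1962,530,192,3367
MultiCASE,statistical,V1705,2018,654,2071,496,145,3367
MultiCASE,rule_based,V1520,2014,1014,2134,16,201,3367
MultiCASE,rule_based,V1603,2015,954,2175,49,187,3367
MultiCASE,rule_based,V1623,2017,954,2175,49,187,3367
MultiCASE,rule_based,V1704,2018,875,2279,60,153,3367
MultiCASE,consensus,V1520,2014,1188,1690,249,239,3367
MultiCASE,consensus,V1603,2015,1139,1733,262,232,3367
MultiCASE,consensus,V1623,2017,1139,1732,496,233,3367
MultiCASE,consensus,V1704,2018,1061,1839,294,173,3367
Lhasa,statistical,V.B,2014,593,2058,553,163,3367
Lhasa,statistical,V.C,2016,741,2029,461,136,3367
Lhasa,statistical,V.D,2018,696,2103,441,127,3367
Lhasa,rule_based,V.A,2012,1006,2361,0,0,3367
Lhasa,rule_based,V.B,2013,1004,2363,0,0,3367
Lhasa,rule_based,V.C,2014,1009,2256,0,102,3367
Lhasa,rule_based,V.D,2014,1009,2256,0,102,3367
Lhasa,rule_based,V.E,2016,997,2274,0,96,3367
Lhasa,rule_based,V.F,2018,1009,2255,0,103,3367
Lhasa,consensus,V.A,2014,1183,1666,346,172,3367
Lhasa,consensus,V.B,2016,1265,1698,267,137,3367
Lhasa,consensus,V.C,2018,1220,1759,256,132,3367
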