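sex,ga_weeks,p10_weight_g
male,24,445
male,25,539
male,26,639
male,27,745
male,28,857
male,29,975
male,30,1100
male,31,1231
male,32,1368
male,33,1511
male,34,1660
male,35,1815
male,36,1976
male,37,2144
male,38,2318
male,39,2498
male,40,2684
male,41,2876
male,42,3075
female,24,427
female,25,517
female,26,613
female,27,715
female,28,823
female,29,936
female,30,1056
female,31,1182
female,32,1313
female,33,1451
female,34,1594
female,35,1742
female,36,1897
female,37,2058
female,38,2225
female,39,2398
female,40,2577
female,41,2761
female,42,2952
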