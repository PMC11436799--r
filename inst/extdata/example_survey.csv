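"field_id","lat","lon","state","district","year","yield_obs","n_rate","p_rate","k_rate","zn_rate","irrigation_count","sowing_doy","variety_class","weather_srad","weather_tmax"
"F00001",26.555,84.3859,"State-1","D03",2019,5.4643,189.943,27.3248,53.057,3.408,8,207,"short",2061.1064,32.528
"F00002",26.771,84.2326,"State-1","D03",2018,4.48,211.9544,8.0197,24.4437,17.137,1,167,"medium",2115.212,32.8983
"F00003",25.4797,84.0689,"State-1","D01",2019,3.6205,21.105,4.1352,11.6538,22.1534,6,190,"long",1858.1948,34.5304
"F00004",25.881,84.0622,"State-1","D01",2019,5.4071,142.0277,46.6803,7.3102,10.2804,6,196,"medium",1839.274,35.4323
"F00005",25.968,84.125,"State-1","D01",2017,4.8928,207.4187,32.2131,31.6174,18.2814,8,168,"medium",1843.648,34.9035
"F00006",25.6905,85.0233,"State-1","D02",2018,5.1299,233.6415,29.4728,24.3146,8.2728,2,154,"medium",1928.703,31.8933
"F00007",25.8669,85.3919,"State-1","D02",2018,4.5716,173.2527,25.5339,25.3042,22.0464,2,155,"short",1914.1727,31.8178
"F00008",25.5603,85.8596,"State-1","D02",2018,4.6041,145.632,10.9799,52.9122,22.6968,1,164,"medium",1910.0125,31.8729
"F00009",26.3045,84.7183,"State-1","D03",2019,4.6656,216.2264,51.3432,13.4766,11.0524,2,205,"long",2095.6473,32.5757
"F00010",25.9993,85.3394,"State-1","D02",2017,5.2554,232.8764,39.3253,34.9316,7.993,6,194,"medium",1860.0586,31.7675
"F00011",26.2933,84.0812,"State-1","D03",2019,4.8265,35.1664,52.5782,20.4888,24.9251,6,206,"medium",2124.9848,32.902
"F00012",26.9034,84.0372,"State-1","D03",2019,5.6423,157.8268,7.5131,28.9559,2.2532,5,192,"medium",2036.4656,32.6064
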