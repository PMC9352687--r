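ID	chrom	loc.start	loc.end	num.mark	seg.mean
MONO001_M1	1	1	6300000	6300	-0.129015
MONO001_M1	1	6300001	9300000	3000	-0.175761
MONO001_M1	1	9300001	10000000	700	-0.149751
MONO001_M1	2	1	10000000	10000	-0.211064
MONO001_M1	3	1	10000000	10000	-0.901041
MONO001_M1	4	1	4900000	4900	-0.164501
MONO001_M1	4	4900001	8200000	3300	-0.825860
MONO001_M1	4	8200001	10000000	1800	-0.181339
MONO001_M1	5	1	1100000	1100	0.604115
MONO001_M1	5	1100001	3300000	2200	1.194550
MONO001_M1	5	3300001	5800000	2500	0.880034
MONO001_M1	5	5800001	9700000	3900	0.210411
MONO001_M1	5	9700001	10000000	300	0.593432
MONO001_M1	6	1	100000	100	-0.244252
MONO001_M1	6	100001	3500000	3400	0.575834
MONO001_M1	6	3500001	3800000	300	1.124117
MONO001_M1	6	3800001	4100000	300	1.332971
MONO001_M1	6	4100001	4500000	400	1.085760
MONO001_M1	6	4500001	10000000	5500	0.635457
MONO001_M1	7	1	10000000	10000	-0.194656
MONO001_M1	8	1	10000000	10000	-0.197506
MONO001_P1	1	1	6300000	6300	-0.024393
MONO001_P1	1	6300001	9300000	3000	-0.213578
MONO001_P1	1	9300001	10000000	700	-0.076316
MONO001_P1	2	1	10000000	10000	-0.325360
MONO001_P1	3	1	10000000	10000	0.237391
MONO001_P1	4	1	4900000	4900	-0.054850
MONO001_P1	4	4900001	8200000	3300	-0.018448
MONO001_P1	4	8200001	10000000	1800	-0.073305
MONO001_P1	5	1	1100000	1100	0.071886
MONO001_P1	5	1100001	3300000	2200	0.661204
MONO001_P1	5	3300001	5800000	2500	0.360764
MONO001_P1	5	5800001	9700000	3900	-0.347578
MONO001_P1	5	9700001	10000000	300	-0.046493
MONO001_P1	6	1	100000	100	-0.035392
MONO001_P1	6	100001	3500000	3400	0.066690
MONO001_P1	6	3500001	3800000	300	0.636526
MONO001_P1	6	3800001	4100000	300	0.920200
MONO001_P1	6	4100001	4500000	400	0.757446
MONO001_P1	6	4500001	10000000	5500	0.101842
MONO001_P1	7	1	10000000	10000	-0.053491
MONO001_P1	8	1	10000000	10000	-0.127028
MONO002_M1	1	1	1500000	1500	-0.028966
MONO002_M1	1	1500001	3100000	1600	-0.682904
MONO002_M1	1	3100001	6800000	3700	-0.008948
MONO002_M1	1	6800001	8100000	1300	-0.817893
MONO002_M1	1	8100001	10000000	1900	0.061749
MONO002_M1	2	1	10000000	10000	0.889116
MONO002_M1	3	1	10000000	10000	0.058938
MONO002_M1	4	1	10000000	10000	-0.633133
MONO002_M1	5	1	1800000	1800	0.099657
MONO002_M1	5	1800001	8900000	7100	-0.083543
MONO002_M1	5	8900001	10000000	1100	0.022099
MONO002_M1	6	1	8200000	8200	-0.636434
MONO002_M1	6	8200001	9100000	900	-2.079338
MONO002_M1	6	9100001	10000000	900	-0.660079
MONO002_M1	7	1	100000	100	-0.003142
MONO002_M1	7	100001	500000	400	0.883958
MONO002_M1	7	500001	10000000	9500	0.145954
MONO002_M1	8	1	7700000	7700	-0.047400
MONO002_M1	8	7700001	9200000	1500	-0.644496
MONO002_M1	8	9200001	10000000	800	-0.105192
MONO002_P1	1	1	1500000	1500	0.016690
MONO002_P1	1	1500001	3100000	1600	-0.707544
MONO002_P1	1	3100001	6800000	3700	-0.533385
MONO002_P1	1	6800001	8100000	1300	-0.703705
MONO002_P1	1	8100001	10000000	1900	-0.007963
MONO002_P1	2	1	10000000	10000	0.299881
MONO002_P1	3	1	10000000	10000	-0.001946
MONO002_P1	4	1	10000000	10000	-0.225506
MONO002_P1	5	1	1800000	1800	0.284747
MONO002_P1	5	1800001	8900000	7100	0.558387
MONO002_P1	5	8900001	10000000	1100	0.301198
MONO002_P1	6	1	8200000	8200	-0.219889
MONO002_P1	6	8200001	9100000	900	-1.067734
MONO002_P1	6	9100001	10000000	900	-0.112563
MONO002_P1	7	1	100000	100	-0.099842
MONO002_P1	7	100001	500000	400	0.872296
MONO002_P1	7	500001	10000000	9500	-0.125201
MONO002_P1	8	1	7700000	7700	-0.031897
MONO002_P1	8	7700001	9200000	1500	-0.736696
MONO002_P1	8	9200001	10000000	800	0.046540
POLY001_M1	1	1	1400000	1400	-0.145961
POLY001_M1	1	1400001	1800000	400	0.020272
POLY001_M1	1	1800001	4200000	2400	0.810271
POLY001_M1	1	4200001	4700000	500	-0.089981
POLY001_M1	1	4700001	5600000	900	0.002236
POLY001_M1	1	5600001	7600000	2000	-0.099487
POLY001_M1	1	7600001	8200000	600	-0.011952
POLY001_M1	1	8200001	9400000	1200	-0.208948
POLY001_M1	1	9400001	10000000	600	-0.201316
POLY001_M1	2	1	200000	200	-0.056471
POLY001_M1	2	200001	7100000	6900	-0.073502
POLY001_M1	2	7100001	10000000	2900	-0.095088
POLY001_M1	3	1	7700000	7700	-0.106546
POLY001_M1	3	7700001	8000000	300	0.099632
POLY001_M1	3	8000001	10000000	2000	-0.098434
POLY001_M1	4	1	10000000	10000	-0.140527
POLY001_M1	5	1	4600000	4600	-0.112772
POLY001_M1	5	4600001	5200000	600	-0.844938
POLY001_M1	5	5200001	10000000	4800	-0.119233
POLY001_M1	6	1	10000000	10000	-0.136320
POLY001_M1	7	1	3200000	3200	-0.162112
POLY001_M1	7	3200001	8300000	5100	0.622631
POLY001_M1	7	8300001	10000000	1700	-0.148919
POLY001_M1	8	1	600000	600	-0.094456
POLY001_M1	8	600001	3200000	2600	0.658880
POLY001_M1	8	3200001	3500000	300	0.747360
POLY001_M1	8	3500001	3700000	200	0.613737
POLY001_M1	8	3700001	5100000	1400	-0.169994
POLY001_M1	8	5100001	6800000	1700	-0.030697
POLY001_M1	8	6800001	10000000	3200	-0.156575
POLY001_P1	1	1	1400000	1400	-0.198528
POLY001_P1	1	1400001	1800000	400	-0.059520
POLY001_P1	1	1800001	4200000	2400	0.740644
POLY001_P1	1	4200001	4700000	500	-0.110351
POLY001_P1	1	4700001	5600000	900	0.041171
POLY001_P1	1	5600001	7600000	2000	-0.018930
POLY001_P1	1	7600001	8200000	600	0.063145
POLY001_P1	1	8200001	9400000	1200	-0.129231
POLY001_P1	1	9400001	10000000	600	-0.174142
POLY001_P1	2	1	200000	200	-0.147767
POLY001_P1	2	200001	7100000	6900	-0.114136
POLY001_P1	2	7100001	10000000	2900	-0.167324
POLY001_P1	3	1	7700000	7700	-0.090167
POLY001_P1	3	7700001	8000000	300	0.179645
POLY001_P1	3	8000001	10000000	2000	-0.168189
POLY001_P1	4	1	10000000	10000	-0.209083
POLY001_P1	5	1	4600000	4600	-0.141407
POLY001_P1	5	4600001	5200000	600	-0.923707
POLY001_P1	5	5200001	10000000	4800	-0.147639
POLY001_P1	6	1	10000000	10000	-0.077168
POLY001_P1	7	1	3200000	3200	-0.123208
POLY001_P1	7	3200001	8300000	5100	0.683359
POLY001_P1	7	8300001	10000000	1700	-0.224436
POLY001_P1	8	1	600000	600	-0.119244
POLY001_P1	8	600001	3200000	2600	0.728436
POLY001_P1	8	3200001	3500000	300	0.892847
POLY001_P1	8	3500001	3700000	200	0.691022
POLY001_P1	8	3700001	5100000	1400	-0.129667
POLY001_P1	8	5100001	6800000	1700	-0.048044
POLY001_P1	8	6800001	10000000	3200	-0.188231
POLY002_M1	1	1	10000000	10000	-0.383410
POLY002_M1	2	1	10000000	10000	-0.278089
POLY002_M1	3	1	10000000	10000	0.711761
POLY002_M1	4	1	4500000	4500	-0.321315
POLY002_M1	4	4500001	7700000	3200	-0.295189
POLY002_M1	4	7700001	10000000	2300	-0.330255
POLY002_M1	5	1	10000000	10000	-0.320163
POLY002_M1	6	1	1400000	1400	-0.242684
POLY002_M1	6	1400001	4500000	3100	0.092943
POLY002_M1	6	4500001	10000000	5500	-0.283975
POLY002_M1	7	1	7100000	7100	-0.300347
POLY002_M1	7	7100001	8900000	1800	-0.081915
POLY002_M1	7	8900001	10000000	1100	-0.391691
POLY002_M1	8	1	1500000	1500	0.454619
POLY002_M1	8	1500001	4300000	2800	0.428142
POLY002_M1	8	4300001	4900000	600	0.983244
POLY002_M1	8	4900001	6200000	1300	0.492429
POLY002_M1	8	6200001	7800000	1600	0.506058
POLY002_M1	8	7800001	9400000	1600	0.562652
POLY002_M1	8	9400001	10000000	600	0.528115
POLY002_P1	1	1	10000000	10000	-0.385553
POLY002_P1	2	1	10000000	10000	-0.375847
POLY002_P1	3	1	10000000	10000	0.625671
POLY002_P1	4	1	4500000	4500	-0.281782
POLY002_P1	4	4500001	7700000	3200	-0.295591
POLY002_P1	4	7700001	10000000	2300	-0.352590
POLY002_P1	5	1	10000000	10000	-0.259389
POLY002_P1	6	1	1400000	1400	-0.292420
POLY002_P1	6	1400001	4500000	3100	-0.022078
POLY002_P1	6	4500001	10000000	5500	-0.310233
POLY002_P1	7	1	7100000	7100	-0.259834
POLY002_P1	7	7100001	8900000	1800	-0.065330
POLY002_P1	7	8900001	10000000	1100	-0.254599
POLY002_P1	8	1	1500000	1500	0.546408
POLY002_P1	8	1500001	4300000	2800	0.602450
POLY002_P1	8	4300001	4900000	600	0.857349
POLY002_P1	8	4900001	6200000	1300	0.469831
POLY002_P1	8	6200001	7800000	1600	0.501893
POLY002_P1	8	7800001	9400000	1600	0.544418
POLY002_P1	8	9400001	10000000	600	0.493318
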