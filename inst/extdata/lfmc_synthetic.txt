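site	plot	point	leaf_type	day	lfmc
W	1	1	GW	0	58.673
W	1	2	GW	0	56.023
W	1	3	GW	0	53.338
W	1	1	GW	15	50.795
W	1	2	GW	15	52.049
W	1	3	GW	15	49.532
W	1	1	GW	30	37.988
W	1	2	GW	30	34.977
W	1	3	GW	30	41.38
W	1	1	GW	44	33.318
W	1	3	GW	44	40.578
W	1	1	GW	59	28.565
W	1	2	GW	59	18.069
W	1	3	GW	59	23.076
W	1	1	GW	74	27.869
W	1	2	GW	74	26.656
W	1	3	GW	74	33.579
W	1	1	GW	89	23.957
W	1	2	GW	89	36.72
W	1	3	GW	89	14.341
W	2	1	GW	0	37.221
W	2	2	GW	0	50.844
W	2	3	GW	0	38.86
W	2	1	GW	15	41.117
W	2	2	GW	15	40.449
W	2	3	GW	15	42.558
W	2	1	GW	30	35.823
W	2	2	GW	30	29.382
W	2	3	GW	30	36.531
W	2	1	GW	44	29.975
W	2	2	GW	44	34.542
W	2	3	GW	44	38.837
W	2	1	GW	59	35.266
W	2	2	GW	59	26.784
W	2	3	GW	59	31.675
W	2	1	GW	74	27.882
W	2	2	GW	74	32.178
W	2	3	GW	74	21.13
W	2	1	GW	89	30.625
W	2	2	GW	89	27.25
W	2	3	GW	89	19.782
W	3	1	GW	0	67.306
W	3	2	GW	0	66.084
W	3	3	GW	0	55.519
W	3	1	GW	15	49.156
W	3	2	GW	15	62.636
W	3	3	GW	15	52.05
W	3	1	GW	30	49.905
W	3	2	GW	30	53.29
W	3	3	GW	30	39.964
W	3	1	GW	44	35.662
W	3	2	GW	44	43.652
W	3	3	GW	44	30.796
W	3	1	GW	59	22.065
W	3	2	GW	59	28.545
W	3	3	GW	59	42.742
W	3	1	GW	74	42.292
W	3	2	GW	74	35.389
W	3	3	GW	74	34.598
W	3	1	GW	89	36.488
W	3	2	GW	89	43.551
W	3	3	GW	89	32.927
E	1	1	GE	0	91.17
E	1	2	GE	0	96.83
E	1	3	GE	0	87.728
E	1	1	GE	15	79.329
E	1	2	GE	15	73.528
E	1	3	GE	15	81.246
E	1	1	GE	30	45.72
E	1	2	GE	30	50.781
E	1	3	GE	30	59.354
E	1	1	GE	44	42.504
E	1	2	GE	44	36.942
E	1	3	GE	44	41.685
E	1	1	GE	59	29.055
E	1	2	GE	59	26.588
E	1	3	GE	59	26.226
E	1	1	GE	74	21.959
E	1	2	GE	74	15.291
E	1	3	GE	74	10.948
E	1	1	GE	89	8.111
E	1	2	GE	89	11.885
E	1	3	GE	89	3.577
E	1	1	SM	0	222.463
E	1	2	SM	0	235.142
E	1	3	SM	0	283.555
E	1	1	SM	15	232.553
E	1	2	SM	15	208.354
E	1	3	SM	15	173.461
E	1	1	SM	30	202.517
E	1	2	SM	30	187.439
E	1	3	SM	30	157.545
E	1	1	SM	44	136.991
E	1	2	SM	44	123.744
E	1	3	SM	44	136.902
E	1	1	SM	59	108.66
E	1	2	SM	59	144.55
E	1	3	SM	59	90.284
E	1	1	SM	74	73.817
E	1	2	SM	74	15.304
E	1	3	SM	74	36.445
E	1	1	SM	89	48.549
E	1	2	SM	89	106.893
E	1	3	SM	89	55.133
E	1	1	SS	0	297.023
E	1	2	SS	0	304.892
E	1	1	SS	15	285.352
E	1	2	SS	15	234.458
E	1	3	SS	15	245.859
E	1	1	SS	30	201.029
E	1	3	SS	30	173.548
E	1	1	SS	44	115.526
E	1	2	SS	44	166.972
E	1	3	SS	44	149.497
E	1	1	SS	59	66.834
E	1	2	SS	59	58.854
E	1	3	SS	59	79.831
E	1	1	SS	74	12.7
E	1	2	SS	74	83.094
E	1	3	SS	74	57.847
E	1	1	SS	89	32.385
E	1	2	SS	89	114.015
E	1	3	SS	89	68.496
E	2	1	GE	0	78.718
E	2	2	GE	0	69.19
E	2	3	GE	0	81.214
E	2	1	GE	15	61.417
E	2	2	GE	15	57.38
E	2	3	GE	15	64.074
E	2	1	GE	30	48.683
E	2	2	GE	30	44.405
E	2	3	GE	30	45.125
E	2	1	GE	44	33.606
E	2	2	GE	44	38.997
E	2	3	GE	44	29.317
E	2	1	GE	59	23.912
E	2	2	GE	59	20.278
E	2	3	GE	59	16.177
E	2	1	GE	74	4.767
E	2	2	GE	74	18.86
E	2	3	GE	74	9.221
E	2	1	GE	89	12.228
E	2	2	GE	89	18.792
E	2	3	GE	89	1.639
E	2	1	SM	0	256.725
E	2	2	SM	0	278.706
E	2	3	SM	0	233.405
E	2	1	SM	15	214.037
E	2	2	SM	15	197.099
E	2	3	SM	15	180.586
E	2	1	SM	30	150.764
E	2	2	SM	30	175.44
E	2	3	SM	30	192.265
E	2	1	SM	44	154.978
E	2	2	SM	44	106.888
E	2	3	SM	44	167.977
E	2	1	SM	59	100.25
E	2	2	SM	59	63.123
E	2	3	SM	59	102.51
E	2	1	SM	74	80.027
E	2	2	SM	74	112.113
E	2	3	SM	74	56.228
E	2	1	SM	89	67.75
E	2	2	SM	89	73.498
E	2	3	SM	89	45.529
E	2	1	SS	0	246.919
E	2	2	SS	0	253.281
E	2	3	SS	0	256.717
E	2	1	SS	15	219.237
E	2	2	SS	15	203.898
E	2	3	SS	15	201.849
E	2	1	SS	30	161.355
E	2	2	SS	30	162.253
E	2	3	SS	30	164.548
E	2	1	SS	44	99.505
E	2	2	SS	44	142.09
E	2	3	SS	44	124.031
E	2	1	SS	59	100.417
E	2	2	SS	59	106.324
E	2	3	SS	59	63.062
E	2	1	SS	74	71.368
E	2	2	SS	74	60.14
E	2	3	SS	74	97.918
E	2	1	SS	89	47.282
E	2	2	SS	89	67.479
E	2	3	SS	89	62.676
E	3	1	GE	0	86.406
E	3	2	GE	0	68.723
E	3	3	GE	0	81.849
E	3	1	GE	15	63.313
E	3	2	GE	15	66.673
E	3	3	GE	15	68.843
E	3	1	GE	30	54.41
E	3	2	GE	30	63.263
E	3	3	GE	30	36.259
E	3	1	GE	44	21.279
E	3	2	GE	44	25.934
E	3	3	GE	44	40.427
E	3	1	GE	59	13.026
E	3	2	GE	59	21.146
E	3	3	GE	59	19.336
E	3	1	GE	74	16.975
E	3	2	GE	74	9.967
E	3	3	GE	74	20.247
E	3	1	GE	89	4.724
E	3	2	GE	89	5.737
E	3	3	GE	89	2.889
E	3	1	SM	0	251.912
E	3	2	SM	0	263.28
E	3	3	SM	0	239.678
E	3	1	SM	15	201.631
E	3	2	SM	15	181.991
E	3	3	SM	15	221.196
E	3	1	SM	30	135.761
E	3	2	SM	30	169.936
E	3	3	SM	30	173.088
E	3	1	SM	44	98.979
E	3	2	SM	44	136.998
E	3	3	SM	44	99.606
E	3	1	SM	59	105.343
E	3	2	SM	59	96.029
E	3	3	SM	59	98.405
E	3	1	SM	74	101.329
E	3	2	SM	74	94.685
E	3	3	SM	74	96.71
E	3	1	SM	89	84.094
E	3	2	SM	89	50.44
E	3	3	SM	89	100.97
E	3	1	SS	0	272.297
E	3	2	SS	0	241.329
E	3	3	SS	0	270.521
E	3	1	SS	15	281.502
E	3	2	SS	15	246.24
E	3	3	SS	15	267.016
E	3	1	SS	30	243.403
E	3	2	SS	30	163.513
E	3	1	SS	44	109.365
E	3	2	SS	44	159.209
E	3	3	SS	44	121.351
E	3	2	SS	59	119.347
E	3	3	SS	59	122.413
E	3	1	SS	74	79.58
E	3	2	SS	74	87.203
E	3	3	SS	74	69.128
E	3	1	SS	89	73.995
E	3	2	SS	89	88.915
E	3	3	SS	89	69.521
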