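position	guide_base	site_base	penalty
1	A	C	0.7149
1	A	G	0.91
1	A	T	0.6849
1	C	A	0.7299
1	C	G	0.6999
1	C	T	0.895
1	G	A	0.94
1	G	C	0.7149
1	G	T	0.6849
1	T	A	0.7299
1	T	C	0.925
1	T	G	0.6999
2	A	C	0.6798
2	A	G	0.865
2	A	T	0.6498
2	C	A	0.6948
2	C	G	0.6648
2	C	T	0.85
2	G	A	0.895
2	G	C	0.6798
2	G	T	0.6498
2	T	A	0.6948
2	T	C	0.88
2	T	G	0.6648
3	A	C	0.6447
3	A	G	0.82
3	A	T	0.6147
3	C	A	0.6597
3	C	G	0.6297
3	C	T	0.805
3	G	A	0.85
3	G	C	0.6447
3	G	T	0.6147
3	T	A	0.6597
3	T	C	0.835
3	T	G	0.6297
4	A	C	0.6096
4	A	G	0.775
4	A	T	0.5796
4	C	A	0.6246
4	C	G	0.5946
4	C	T	0.76
4	G	A	0.805
4	G	C	0.6096
4	G	T	0.5796
4	T	A	0.6246
4	T	C	0.79
4	T	G	0.5946
5	A	C	0.5745
5	A	G	0.73
5	A	T	0.5445
5	C	A	0.5895
5	C	G	0.5595
5	C	T	0.715
5	G	A	0.76
5	G	C	0.5745
5	G	T	0.5445
5	T	A	0.5895
5	T	C	0.745
5	T	G	0.5595
6	A	C	0.5394
6	A	G	0.685
6	A	T	0.5094
6	C	A	0.5544
6	C	G	0.5244
6	C	T	0.67
6	G	A	0.715
6	G	C	0.5394
6	G	T	0.5094
6	T	A	0.5544
6	T	C	0.7
6	T	G	0.5244
7	A	C	0.5043
7	A	G	0.64
7	A	T	0.4743
7	C	A	0.5193
7	C	G	0.4893
7	C	T	0.625
7	G	A	0.67
7	G	C	0.5043
7	G	T	0.4743
7	T	A	0.5193
7	T	C	0.655
7	T	G	0.4893
8	A	C	0.4692
8	A	G	0.595
8	A	T	0.4392
8	C	A	0.4842
8	C	G	0.4542
8	C	T	0.58
8	G	A	0.625
8	G	C	0.4692
8	G	T	0.4392
8	T	A	0.4842
8	T	C	0.61
8	T	G	0.4542
9	A	C	0.4341
9	A	G	0.55
9	A	T	0.4041
9	C	A	0.4491
9	C	G	0.4191
9	C	T	0.535
9	G	A	0.58
9	G	C	0.4341
9	G	T	0.4041
9	T	A	0.4491
9	T	C	0.565
9	T	G	0.4191
10	A	C	0.399
10	A	G	0.505
10	A	T	0.369
10	C	A	0.414
10	C	G	0.384
10	C	T	0.49
10	G	A	0.535
10	G	C	0.399
10	G	T	0.369
10	T	A	0.414
10	T	C	0.52
10	T	G	0.384
11	A	C	0.3639
11	A	G	0.46
11	A	T	0.3339
11	C	A	0.3789
11	C	G	0.3489
11	C	T	0.445
11	G	A	0.49
11	G	C	0.3639
11	G	T	0.3339
11	T	A	0.3789
11	T	C	0.475
11	T	G	0.3489
12	A	C	0.3288
12	A	G	0.415
12	A	T	0.2988
12	C	A	0.3438
12	C	G	0.3138
12	C	T	0.4
12	G	A	0.445
12	G	C	0.3288
12	G	T	0.2988
12	T	A	0.3438
12	T	C	0.43
12	T	G	0.3138
13	A	C	0.2937
13	A	G	0.37
13	A	T	0.2637
13	C	A	0.3087
13	C	G	0.2787
13	C	T	0.355
13	G	A	0.4
13	G	C	0.2937
13	G	T	0.2637
13	T	A	0.3087
13	T	C	0.385
13	T	G	0.2787
14	A	C	0.2586
14	A	G	0.325
14	A	T	0.2286
14	C	A	0.2736
14	C	G	0.2436
14	C	T	0.31
14	G	A	0.355
14	G	C	0.2586
14	G	T	0.2286
14	T	A	0.2736
14	T	C	0.34
14	T	G	0.2436
15	A	C	0.2235
15	A	G	0.28
15	A	T	0.1935
15	C	A	0.2385
15	C	G	0.2085
15	C	T	0.265
15	G	A	0.31
15	G	C	0.2235
15	G	T	0.1935
15	T	A	0.2385
15	T	C	0.295
15	T	G	0.2085
16	A	C	0.1884
16	A	G	0.235
16	A	T	0.1584
16	C	A	0.2034
16	C	G	0.1734
16	C	T	0.22
16	G	A	0.265
16	G	C	0.1884
16	G	T	0.1584
16	T	A	0.2034
16	T	C	0.25
16	T	G	0.1734
17	A	C	0.1533
17	A	G	0.19
17	A	T	0.1233
17	C	A	0.1683
17	C	G	0.1383
17	C	T	0.175
17	G	A	0.22
17	G	C	0.1533
17	G	T	0.1233
17	T	A	0.1683
17	T	C	0.205
17	T	G	0.1383
18	A	C	0.1182
18	A	G	0.145
18	A	T	0.0882
18	C	A	0.1332
18	C	G	0.1032
18	C	T	0.13
18	G	A	0.175
18	G	C	0.1182
18	G	T	0.0882
18	T	A	0.1332
18	T	C	0.16
18	T	G	0.1032
19	A	C	0.0831
19	A	G	0.1
19	A	T	0.0531
19	C	A	0.0981
19	C	G	0.0681
19	C	T	0.085
19	G	A	0.13
19	G	C	0.0831
19	G	T	0.0531
19	T	A	0.0981
19	T	C	0.115
19	T	G	0.0681
20	A	C	0.048
20	A	G	0.055
20	A	T	0.02
20	C	A	0.063
20	C	G	0.033
20	C	T	0.04
20	G	A	0.085
20	G	C	0.048
20	G	T	0.02
20	T	A	0.063
20	T	C	0.07
20	T	G	0.033
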