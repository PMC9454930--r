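age	sex	qx
50	male	0.00273934364046935
51	male	0.00296463947031733
52	male	0.00321607214593045
53	male	0.00349666603447807
54	male	0.00380979354237665
55	male	0.00415921469466685
56	male	0.00454912109873451
57	male	0.00498418474900908
58	male	0.00546961216945063
59	male	0.00601120443238634
60	male	0.00661542363500245
61	male	0.00728946645775297
62	male	0.00804134547101776
63	male	0.00887997889603187
64	male	0.0098152895614646
65	male	0.0108583138254673
66	male	0.0120213212511915
67	male	0.0133179458274393
68	male	0.0147633295098094
69	male	0.0163742788145751
70	male	0.0181694351190037
71	male	0.0201694591972248
72	male	0.0223972303368514
73	male	0.0248780601222345
74	male	0.0276399206157133
75	male	0.0307136861947905
76	male	0.0341333876822298
77	male	0.0379364766039328
78	male	0.042164096386435
79	male	0.0468613560161332
80	male	0.0520776000739185
81	male	0.0578666670736195
82	male	0.0642871256077555
83	male	0.0714024748742254
84	male	0.0792812926582815
85	male	0.0879973097183047
86	male	0.0976293847304825
87	male	0.108261348474236
88	male	0.119981679822207
89	male	0.132882969442874
90	male	0.14706112014138
91	male	0.162614225812452
92	male	0.179641064613465
93	male	0.198239136999185
94	male	0.218502176833749
95	male	0.240517065446971
96	male	0.264360086227246
97	male	0.290092473628876
98	male	0.317755238277121
99	male	0.347363292497196
100	male	0.378898961486871
101	male	0.412305047530185
102	male	0.447477720002435
103	male	0.484259632069128
104	male	0.52243381178656
105	male	0.561719030993792
106	male	0.601767502527034
107	male	0.642165868069919
108	male	0.682440478369002
109	male	0.722067888650312
110	male	1
50	female	0.00147303695613588
51	female	0.0016093512949199
52	female	0.00176149402156711
53	female	0.00193130022579568
54	female	0.00212081704968681
55	female	0.00233232801849292
56	female	0.0025683801205576
57	female	0.00283181393641252
58	female	0.00312579714722483
59	female	0.00345386178521256
60	female	0.00381994562342303
61	female	0.00422843813929685
62	female	0.00468423152555741
63	female	0.00519277726288081
64	female	0.00576014881106768
65	female	0.006393111018411
66	female	0.00709919689170735
67	female	0.00788679241065859
68	female	0.00876523010857266
69	female	0.00974489217408636
70	female	0.0108373238532324
71	female	0.0120553579438463
72	female	0.0134132511703023
73	female	0.0149268331999222
74	female	0.0166136690055074
75	female	0.0184932351819596
76	female	0.0205871106770946
77	female	0.0229191821832309
78	female	0.0255158641392595
79	female	0.0284063328913521
80	female	0.0316227740285437
81	female	0.0352006412164281
82	female	0.0391789239619269
83	female	0.0436004206123882
84	female	0.0485120114745706
85	female	0.053964925178702
86	female	0.0600149892495815
87	female	0.0667228532162265
88	female	0.0741541694283138
89	female	0.0823797129895093
90	female	0.0914754178128099
91	female	0.101522300720483
92	female	0.112606239756377
93	female	0.124817566512859
94	female	0.138250425445102
95	female	0.153001846118636
96	female	0.169170467546327
97	female	0.186854847873835
98	female	0.206151288611614
99	female	0.227151101686452
100	female	0.249937251520858
101	female	0.274580315345705
102	female	0.301133725704644
103	female	0.329628292749947
104	female	0.36006605386054
105	female	0.392413567663198
106	female	0.426594861372979
107	female	0.462484355586882
108	female	0.49990022751066
109	female	0.538598825796967
110	female	1
50	total	0.00196833390186646
51	total	0.00213894338940623
52	total	0.00232935657014421
53	total	0.00254186771048581
54	total	0.00277903576893879
55	total	0.00304371466322684
56	total	0.00333908693160423
57	total	0.00366870115242668
58	total	0.00403651352090317
59	total	0.00444693401907414
60	total	0.00490487765425685
61	total	0.00541582128217921
62	total	0.005985866573326
63	total	0.00662180972399984
64	total	0.00733121855630547
65	total	0.00812251769246264
66	total	0.00900508252680765
67	total	0.00998934275136254
68	total	0.0110868962149916
69	total	0.0123106339081958
70	total	0.0136748768607229
71	total	0.015195525711342
72	total	0.0168902236507015
73	total	0.0187785333396805
74	total	0.0208821282552153
75	total	0.0232249986987637
76	total	0.0258336724015462
77	total	0.0287374492540011
78	total	0.0319686491485447
79	total	0.0355628712238351
80	total	0.0395592618989062
81	total	0.0440007879442159
82	total	0.0489345094050915
83	total	0.0544118454163781
84	total	0.0604888237647386
85	total	0.0672263024026318
86	total	0.0746901479300913
87	total	0.0829513522749908
88	total	0.0920860643684844
89	total	0.102175508500328
90	total	0.113305755255846
91	total	0.125567304547429
92	total	0.139054433409678
93	total	0.153864254201822
94	total	0.170095422096683
95	total	0.187846424899106
96	total	0.20721338428646
97	total	0.228287296816218
98	total	0.251150647245524
99	total	0.275873338078476
100	total	0.302507900512989
101	total	0.331083986249129
102	total	0.361602190352044
103	total	0.39402732584744
104	total	0.428281363583884
105	total	0.464236367124608
106	total	0.501707890112304
107	total	0.540449456163385
108	total	0.58014889580778
109	total	0.620427449680226
110	total	1
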