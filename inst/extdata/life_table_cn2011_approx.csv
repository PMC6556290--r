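age,qx
0,0.00152
1,0.00152210341836151
2,0.0015244280551632
3,0.00152699717615152
4,0.00152983649395283
5,0.001532974425414
6,0.00153644237600781
7,0.00154027505414941
8,0.00154451081856985
9,0.00154919206222314
10,0.00155436563656918
11,0.00156008332047893
12,0.00156640233845473
13,0.00157338593335239
14,0.00158110399933689
15,0.00158963378140676
16,0.0015990606484879
17,0.00160947894783454
18,0.00162099294928826
19,0.00163371788884559
20,0.00164778112197861
21,0.00166332339825135
22,0.00168050026998868
23,0.00169948364909629
24,0.00172046352761283
25,0.00174364987921407
26,0.00176927476070003
27,0.00179759463449746
28,0.00182889293542194
29,0.00186348290738886
30,0.00190171073846375
31,0.00194395902562883
32,0.00199065060394219
33,0.00204225277841316
34,0.00209928200094794
35,0.00216230903917385
36,0.00223196468887356
37,0.00230894608720135
38,0.00239402368986602
39,0.0024880489821106
40,0.00259196300066288
41,0.00270680575194724
42,0.0028337266208185
43,0.00297399587399192
44,0.00312901737329936
45,0.00330034262601044
46,0.00348968631283868
47,0.00369894344904247
48,0.0039302083503747
49,0.00418579559369871
50,0.00446826318205153
51,0.00478043814599804
52,0.00512544483750303
53,0.00550673619949584
54,0.00592812832408374
55,0.00639383864528441
56,0.00690852814852306
57,0.00747734801934121
58,0.00810599119819298
59,0.00880074935730658
60,0.0095685758698547
61,0.0104171554016503
62,0.0113549808218651
63,0.0123914382025186
64,0.0135369007574416
65,0.0148028326608872
66,0.0162019037848395
67,0.0177481165033509
68,0.0194569458330084
69,0.0213454943121005
70,0.0234326631685692
71,0.0257393414898516
72,0.0282886152878884
73,0.0311059985516909
74,0.0342196885999185
75,0.0376608482891213
76,0.0414639179020824
77,0.0456669598377442
78,0.05031203955249
79,0.0554456465653702
80,0.0611191597408346
81,0.0673893615056768
82,0.0743190061466472
83,0.0819774478764463
84,0.0904413349539972
85,0.0997953768059827
86,0.11013319182726
87,0.121558244345221
88,0.134184880125558
89,0.14813947078312
90,0.163561678551508
91,0.18060585406965
92,0.199442581174879
93,0.220260384163304
94,0.24326761460434
95,0.268694536593237
96,0.296795631311546
97,0.327852143960309
98,0.362174898556571
99,0.400107408764606
100,0.442029315896134
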