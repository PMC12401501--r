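age,probability
0,0.00413
1,0.00102547743297123
2,0.000335353278931944
3,0.000184209347752573
4,0.000153608422719798
5,0.000150212163277112
6,0.000153224315647441
7,0.000158037944299583
8,0.000163661724453514
9,0.0001699146925392
10,0.00017680066615916
11,0.00018436904911831
12,0.000192684202149279
13,0.000201819080232548
14,0.000211854331010011
15,0.000222878662798894
16,0.000234989551990541
17,0.000248294087804007
18,0.000262909915389492
19,0.000278966275251087
20,0.000296605145866109
21,0.000315982499088354
22,0.000337269679320985
23,0.000360654918628694
24,0.000386345001180796
25,0.000414567091741827
26,0.000445570744377806
27,0.000479630109140091
28,0.000517046356239448
29,0.000558150339146091
30,0.000603305520164196
31,0.00065291118435029
32,0.000707405970194619
33,0.000767271748285575
34,0.000833037882254309
35,0.000905285909676957
36,0.000984654684325398
37,0.00107184602523695
38,0.00116763092255492
39,0.00127285635501525
40,0.00138845277936289
41,0.00151544235792317
42,0.00165494799708049
43,0.00180820327658716
44,0.00197656335750247
45,0.00216151696521539
46,0.00236469955351097
47,0.00258790776608374
48,0.00283311532337432
49,0.00310249047520843
50,0.00339841517356371
51,0.00372350613499949
52,0.00408063797899436
53,0.0044729686467923
54,0.00490396732552392
55,0.00537744512452196
56,0.00589758877508667
57,0.00646899765169147
58,0.00709672444198926
59,0.0077863198252442
60,0.0085438815542584
61,0.00937610837480082
62,0.0102903592593214
63,0.0112947184787248
64,0.0123980670876022
65,0.0136101614550286
66,0.0149417195353362
67,0.0164045156417129
68,0.0180114845606628
69,0.019776835927961
70,0.0217161798774748
71,0.0238466650738987
72,0.0261871303499623
73,0.0287582712889628
74,0.0315828232256284
75,0.0346857622835016
76,0.0380945262265153
77,0.0418392570776441
78,0.0459530676499883
79,0.0504723343470941
80,0.0554370188215986
81,0.0608910213364692
82,0.0668825689534371
83,0.073464641981184
84,0.0806954424541539
85,0.0886389087845176
86,0.0973652811381034
87,0.106951722533637
88,0.117483001157365
89,0.12905223992643
90,0.14176173992903
91,0.15572388502262
92,0.171062135589092
93,0.187912120234211
94,0.20642283508466
95,0.226757961287515
96,0.249097312362117
97,0.273638424202587
98,0.300598301790578
99,0.330215338063599
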