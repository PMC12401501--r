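age,category,value
0,ga_le28,60
1,ga_le28,51.7817706090784
2,ga_le28,44.7082750202214
3,ga_le28,38.6200609456846
4,ga_le28,33.3798865295476
5,ga_le28,28.8696266117199
6,ga_le28,24.9876099246954
7,ga_le28,21.6463271975582
8,ga_le28,18.7704585028199
9,ga_le28,16.2951753781076
10,ga_le28,14.1646794487574
11,ga_le28,12.3309446086245
12,ga_le28,10.7526344050736
13,ga_le28,9.3941702236043
14,ga_le28,8.22492926692593
15,ga_le28,7.21855424915
16,ga_le28,6.35235924407534
17,ga_le28,5.60681829406804
18,ga_le28,4.96512525164524
19,ga_le28,4.41281493161547
20,ga_le28,3.93743703370397
21,ga_le28,3.52827548515537
22,ga_le28,3.17610687667316
23,ga_le28,2.87299254630601
24,ga_le28,2.61209962439026
25,ga_le28,2.38754700550454
26,ga_le28,2.19427277530246
27,ga_le28,2.02792010373012
28,ga_le28,1.88473903240818
29,ga_le28,1.76150194224831
30,ga_le28,1.6554307957563
31,ga_le28,1.56413451390207
32,ga_le28,1.48555507589218
33,ga_le28,1.41792112681408
34,ga_le28,1.35970804736542
35,ga_le28,1.3096035855517
36,ga_le28,1.26647827561415
37,ga_le28,1.22935997736509
38,ga_le28,1.19741196199081
39,ga_le28,1.16991405032721
40,ga_le28,1.14624637842332
41,ga_le28,1.12587542443222
42,ga_le28,1.10834198184471
43,ga_le28,1.09325080795544
44,ga_le28,1.08026171421533
45,ga_le28,1.06908189762668
0,ga_28_32,15
1,ga_28_32,13.0499116699508
2,ga_28_32,11.371455089544
3,ga_28_32,9.92679412270483
4,ga_28_32,8.68336290531637
5,ga_28_32,7.61313173837421
6,ga_28_32,6.69197523636839
7,ga_28_32,5.89912848755617
8,ga_28_32,5.21671896677083
9,ga_28_32,4.62936364904248
10,ga_28_32,4.12382224207802
11,ga_28_32,3.68869872069056
12,ga_28_32,3.31418443510221
13,ga_28_32,2.99183700221119
14,ga_28_32,2.71438999554175
15,ga_28_32,2.4755891438661
16,ga_28_32,2.27005134605178
17,ga_28_32,2.09314332401614
18,ga_28_32,1.9408771783565
19,ga_28_32,1.80982049224774
20,ga_28_32,1.6970189571501
21,ga_28_32,1.59992977613856
22,ga_28_32,1.51636434361736
23,ga_28_32,1.44443890929295
24,ga_28_32,1.3825321142621
25,ga_28_32,1.32924844198413
26,ga_28_32,1.28338676024126
27,ga_28_32,1.24391324495291
28,ga_28_32,1.20993807548669
29,ga_28_32,1.18069537612672
30,ga_28_32,1.15552595153539
31,ga_28_32,1.13386242702761
32,ga_28_32,1.11521645868628
33,ga_28_32,1.09916772500673
34,ga_28_32,1.08535445191722
35,ga_28_32,1.07346525758854
36,ga_28_32,1.06323213319658
37,ga_28_32,1.05442440140867
38,ga_28_32,1.0468435164046
39,ga_28_32,1.04031858821324
40,ga_28_32,1.03470253047333
41,ga_28_32,1.02986874478053
42,ga_28_32,1.0257082668784
43,ga_28_32,1.02212731036231
44,ga_28_32,1.01904515252567
45,ga_28_32,1.01639231469108
0,ga_32_34,6
1,ga_32_34,5.30353988212529
2,ga_32_34,4.70409110340859
3,ga_32_34,4.18814075810887
4,ga_32_34,3.74405818047013
5,ga_32_34,3.36183276370507
6,ga_32_34,3.032848298703
7,ga_32_34,2.74968874555578
8,ga_32_34,2.50597105956101
9,ga_32_34,2.29620130322946
10,ga_32_34,2.11565080074215
11,ga_32_34,1.96024954310377
12,ga_32_34,1.82649444110793
13,ga_32_34,1.71137035793257
14,ga_32_34,1.61228214126491
15,ga_32_34,1.52699612280932
16,ga_32_34,1.45358976644706
17,ga_32_34,1.39040833000577
18,ga_32_34,1.33602756369875
19,ga_32_34,1.28922160437419
20,ga_32_34,1.24893534183932
21,ga_32_34,1.2142606343352
22,ga_32_34,1.1844158370062
23,ga_32_34,1.15872818189034
24,ga_32_34,1.13661861223646
25,ga_32_34,1.11758872928005
26,ga_32_34,1.10120955722902
27,ga_32_34,1.08711187319747
28,ga_32_34,1.07497788410239
29,ga_32_34,1.0645340629024
30,ga_32_34,1.05554498269121
31,ga_32_34,1.04780800965272
32,ga_32_34,1.0411487352451
33,ga_32_34,1.03541704464526
34,ga_32_34,1.03048373282758
35,ga_32_34,1.02623759199591
36,ga_32_34,1.02258290471306
37,ga_32_34,1.01943728621738
38,ga_32_34,1.01672982728736
39,ga_32_34,1.01439949579044
40,ga_32_34,1.01239376088333
41,ga_32_34,1.01066740885019
42,ga_32_34,1.00918152388514
43,ga_32_34,1.00790261084368
44,ga_32_34,1.00680184018774
45,ga_32_34,1.00585439810396
0,ga_34_37,2.5
1,ga_34_37,2.29106196463759
2,ga_34_37,2.11122733102258
3,ga_34_37,1.95644222743266
4,ga_34_37,1.82321745414104
5,ga_34_37,1.70854982911152
6,ga_34_37,1.6098544896109
7,ga_34_37,1.52490662366673
8,ga_34_37,1.4517913178683
9,ga_34_37,1.38886039096884
10,ga_34_37,1.33469524022264
11,ga_34_37,1.28807486293113
12,ga_34_37,1.24794833233238
13,ga_34_37,1.21341110737977
14,ga_34_37,1.18368464237947
15,ga_34_37,1.1580988368428
16,ga_34_37,1.13607692993412
17,ga_34_37,1.11712249900173
18,ga_34_37,1.10080826910962
19,ga_34_37,1.08676648131226
20,ga_34_37,1.0746806025518
21,ga_34_37,1.06427819030056
22,ga_34_37,1.05532475110186
23,ga_34_37,1.0476184545671
24,ga_34_37,1.04098558367094
25,ga_34_37,1.03527661878401
26,ga_34_37,1.03036286716871
27,ga_34_37,1.02613356195924
28,ga_34_37,1.02249336523072
29,ga_34_37,1.01936021887072
30,ga_34_37,1.01666349480736
31,ga_34_37,1.01434240289582
32,ga_34_37,1.01234462057353
33,ga_34_37,1.01062511339358
34,ga_34_37,1.00914511984827
35,ga_34_37,1.00787127759877
36,ga_34_37,1.00677487141392
37,ga_34_37,1.00583118586521
38,ga_34_37,1.00501894818621
39,ga_34_37,1.00431984873713
40,ga_34_37,1.003718128265
41,ga_34_37,1.00320022265506
42,ga_34_37,1.00275445716554
43,ga_34_37,1.0023707832531
44,ga_34_37,1.00204055205632
45,ga_34_37,1.00175631943119
0,ga_gt37,1
1,ga_gt37,1
2,ga_gt37,1
3,ga_gt37,1
4,ga_gt37,1
5,ga_gt37,1
6,ga_gt37,1
7,ga_gt37,1
8,ga_gt37,1
9,ga_gt37,1
10,ga_gt37,1
11,ga_gt37,1
12,ga_gt37,1
13,ga_gt37,1
14,ga_gt37,1
15,ga_gt37,1
16,ga_gt37,1
17,ga_gt37,1
18,ga_gt37,1
19,ga_gt37,1
20,ga_gt37,1
21,ga_gt37,1
22,ga_gt37,1
23,ga_gt37,1
24,ga_gt37,1
25,ga_gt37,1
26,ga_gt37,1
27,ga_gt37,1
28,ga_gt37,1
29,ga_gt37,1
30,ga_gt37,1
31,ga_gt37,1
32,ga_gt37,1
33,ga_gt37,1
34,ga_gt37,1
35,ga_gt37,1
36,ga_gt37,1
37,ga_gt37,1
38,ga_gt37,1
39,ga_gt37,1
40,ga_gt37,1
41,ga_gt37,1
42,ga_gt37,1
43,ga_gt37,1
44,ga_gt37,1
45,ga_gt37,1
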