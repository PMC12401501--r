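age,category,value
0,ga_le28,30100
1,ga_le28,16600
2,ga_le28,9175
3,ga_le28,5091.25
4,ga_le28,2845.1875
5,ga_le28,1609.853125
6,ga_le28,930.41921875
7,ga_le28,556.7305703125
8,ga_le28,351.201813671875
9,ga_le28,238.160997519531
0,ga_28_32,15100
1,ga_28_32,8350
2,ga_28_32,4637.5
3,ga_28_32,2595.625
4,ga_28_32,1472.59375
5,ga_28_32,854.9265625
6,ga_28_32,515.209609375
7,ga_28_32,328.36528515625
8,ga_28_32,225.600906835938
9,ga_28_32,169.080498759766
0,ga_32_34,8100
1,ga_32_34,4500
2,ga_32_34,2520
3,ga_32_34,1431
4,ga_32_34,832.05
5,ga_32_34,502.6275
6,ga_32_34,321.445125
7,ga_32_34,221.79481875
8,ga_32_34,166.9871503125
9,ga_32_34,136.842932671875
0,ga_34_37,2600
1,ga_34_37,1475
2,ga_34_37,856.25
3,ga_34_37,515.9375
4,ga_34_37,328.765625
5,ga_34_37,225.82109375
6,ga_34_37,169.2016015625
7,ga_34_37,138.060880859375
8,ga_34_37,120.933484472656
9,ga_34_37,111.513416459961
0,ga_gt37,500
1,ga_gt37,320
2,ga_gt37,221
3,ga_gt37,166.55
4,ga_gt37,136.6025
5,ga_gt37,120.131375
6,ga_gt37,111.07225625
7,ga_gt37,106.0897409375
8,ga_gt37,103.349357515625
9,ga_gt37,101.842146633594
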