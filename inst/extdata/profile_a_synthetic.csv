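"bin_hz","power"
0,1.63769287474912e-05
172.265625,0.000151359035972619
344.53125,0.000438252301064846
516.796875,0.000504050487117184
689.0625,0.000455870850512921
861.328125,0.000494218277917756
1033.59375,0.000466166136746598
1205.859375,0.000450276036277964
1378.125,0.000438465553307212
1550.390625,0.000462532956684008
1722.65625,0.000521039583895259
1894.921875,0.000636579931570223
2067.1875,0.000767249621539553
2239.453125,0.000973000423879174
2411.71875,0.00137151611557101
2583.984375,0.00178873523784522
2756.25,0.00272130604054709
2928.515625,0.00453142767327803
3100.78125,0.00715374746020286
3273.046875,0.0124415691790173
3445.3125,0.0246607912159106
3617.578125,0.0569318201685513
3789.84375,0.160777386071805
3962.109375,0.283689036440231
4134.375,0.22387591378282
4306.640625,0.0890449631199144
4478.90625,0.0334701481891475
4651.171875,0.0164958590949914
4823.4375,0.00921735723627536
4995.703125,0.00564273795005397
5167.96875,0.00357365107298226
5340.234375,0.00248162206645276
5512.5,0.00176511251569192
5684.765625,0.00135490838390432
5857.03125,0.000932863538483964
6029.296875,0.000622986085620303
6201.5625,0.000465219769878264
6373.828125,0.000494347323005928
6546.09375,0.000529702099867761
6718.359375,0.000554864086555651
6890.625,0.000495877455722172
7062.890625,0.00046699427044781
7235.15625,0.000421013987916654
7407.421875,0.000491867975712601
7579.6875,0.000502067849912366
7751.953125,0.000536601228183889
7924.21875,0.000545834817219689
8096.484375,0.000459988791969502
8268.75,0.000485519461856128
8441.015625,0.00051265693548374
8613.28125,0.000477963032220827
8785.546875,0.000510527657841603
8957.8125,0.000539690135442778
9130.078125,0.00056513776027948
9302.34375,0.000562836142042601
9474.609375,0.000551557575124217
9646.875,0.000560890749070709
9819.140625,0.000540361689714142
9991.40625,0.000616225427627117
10163.671875,0.000601010853126847
10335.9375,0.000459920636947377
10508.203125,0.00048507814334635
10680.46875,0.000575007523078696
10852.734375,0.000618958470677179
11025,0.000509402441341405
11197.265625,0.000504836630216589
11369.53125,0.000524461272170707
11541.796875,0.000572572207160058
11714.0625,0.000583466337093627
11886.328125,0.000522495600080686
12058.59375,0.000619888445207731
12230.859375,0.000579281018107972
12403.125,0.000533888591816568
12575.390625,0.000482327305812948
12747.65625,0.000453981355318093
12919.921875,0.000486035673053229
13092.1875,0.00054029163918245
13264.453125,0.000520802754594283
13436.71875,0.000530681859852186
13608.984375,0.000535619694092303
13781.25,0.000553861624310412
13953.515625,0.000498628331258278
14125.78125,0.000454974379238139
14298.046875,0.000479207443421975
14470.3125,0.000559779312111228
14642.578125,0.000561081941374443
14814.84375,0.000514267357112297
14987.109375,0.000485154788482088
15159.375,0.000499422438367655
15331.640625,0.000513534154993225
15503.90625,0.000514387359638833
15676.171875,0.000446855697989488
15848.4375,0.000451679552951641
16020.703125,0.000500814796016625
16192.96875,0.000481674654822993
16365.234375,0.000539166348865835
16537.5,0.000541396546660637
16709.765625,0.000514890996354456
16882.03125,0.000520637841190624
17054.296875,0.000502320752986206
17226.5625,0.000440963633358771
17398.828125,0.000434111793438072
17571.09375,0.000526934174843288
17743.359375,0.00056585458794678
17915.625,0.000521373368500719
18087.890625,0.000518813686185324
18260.15625,0.000564134920265059
18432.421875,0.000481759343798628
18604.6875,0.00051172715202752
18776.953125,0.000520655664068853
18949.21875,0.000509487342229157
19121.484375,0.000580409766881962
19293.75,0.000613195758165425
19466.015625,0.000593501518632685
19638.28125,0.000577928512385955
19810.546875,0.000576172531690816
19982.8125,0.000577302300348233
20155.078125,0.000587504341672318
20327.34375,0.000577393122428883
20499.609375,0.000507000640542989
20671.875,0.000464219726995504
20844.140625,0.000443936200817882
21016.40625,0.00049055925349136
21188.671875,0.000547159176431347
21360.9375,0.000530244929298593
21533.203125,0.000561841295971058
21705.46875,0.000529191294899851
21877.734375,0.000522446670930447
22050,0.000541789533701035
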