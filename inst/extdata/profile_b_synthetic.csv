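"bin_hz","power"
0,1.74004810280511e-05
172.265625,0.000172574031397211
344.53125,0.000440339430035764
516.796875,0.000512319495059422
689.0625,0.000348549348204498
861.328125,0.000335911429606973
1033.59375,0.000505008794408381
1205.859375,0.000491118627791225
1378.125,0.000485009220275744
1550.390625,0.000570065205772253
1722.65625,0.000545896908866039
1894.921875,0.000532394463976593
2067.1875,0.000648424025300086
2239.453125,0.000920087590633007
2411.71875,0.00109254601751133
2583.984375,0.00122848452521128
2756.25,0.00166755151586352
2928.515625,0.00246793365139332
3100.78125,0.00391650950945764
3273.046875,0.00599450364445588
3445.3125,0.00973855572080137
3617.578125,0.0180049498204991
3789.84375,0.0357798370316261
3962.109375,0.0844525340553354
4134.375,0.188085617424145
4306.640625,0.254148419800613
4478.90625,0.178509750649454
4651.171875,0.0781413901032765
4823.4375,0.0338147151866474
4995.703125,0.0174858066018578
5167.96875,0.0106496278088257
5340.234375,0.00639576213338816
5512.5,0.00401903499706227
5684.765625,0.00275637631122209
5857.03125,0.00165108403845793
6029.296875,0.00105642615964695
6201.5625,0.00090853680307608
6373.828125,0.00102382038137726
6546.09375,0.000682586249675022
6718.359375,0.000552526187295895
6890.625,0.000659148864941575
7062.890625,0.000626329792260897
7235.15625,0.000645966771629879
7407.421875,0.000654243687925435
7579.6875,0.000513317600745543
7751.953125,0.000409250309549077
7924.21875,0.000395912685112618
8096.484375,0.000431717724088768
8268.75,0.000571645760717267
8441.015625,0.000504864169207838
8613.28125,0.000453500079946277
8785.546875,0.000517856846702397
8957.8125,0.000629407066515718
9130.078125,0.000469715867334713
9302.34375,0.000428353005793746
9474.609375,0.000495146023345771
9646.875,0.000468184495775571
9819.140625,0.000594105560512893
9991.40625,0.000622524485910781
10163.671875,0.000609656807374162
10335.9375,0.000497401912855481
10508.203125,0.000465417650114629
10680.46875,0.000497942014548029
10852.734375,0.000502808230272249
11025,0.000675055347079046
11197.265625,0.000735508227550253
11369.53125,0.000479314329393402
11541.796875,0.000416498815967645
11714.0625,0.000534829129790425
11886.328125,0.00051995051935326
12058.59375,0.000413161700806417
12230.859375,0.00054681743532299
12403.125,0.000583435736545185
12575.390625,0.000657134385581062
12747.65625,0.000514796426694231
12919.921875,0.000568079282435565
13092.1875,0.000504177138031806
13264.453125,0.000510472178540957
13436.71875,0.000478034014888001
13608.984375,0.000447947012738424
13781.25,0.000513186617401078
13953.515625,0.000587808539404547
14125.78125,0.000683887313867039
14298.046875,0.000687776334412342
14470.3125,0.000622067713369112
14642.578125,0.000690431842903588
14814.84375,0.000751986067973071
14987.109375,0.000643680605923701
15159.375,0.000552395230466377
15331.640625,0.000602887571790568
15503.90625,0.000517868267936617
15676.171875,0.000551326804599077
15848.4375,0.00067489854700679
16020.703125,0.000493973386263625
16192.96875,0.000580348433286385
16365.234375,0.000584483561972459
16537.5,0.000386997311928805
16709.765625,0.000502906220122268
16882.03125,0.000694610212797951
17054.296875,0.000667978468469661
17226.5625,0.000540089472998025
17398.828125,0.000560397710209278
17571.09375,0.000405823335124104
17743.359375,0.000616280806577878
17915.625,0.000749570560802435
18087.890625,0.000609722989039072
18260.15625,0.000555441236667918
18432.421875,0.000462794051278356
18604.6875,0.000486616268039003
18776.953125,0.000581733824900806
18949.21875,0.000484799504532778
19121.484375,0.000572339208010914
19293.75,0.000674707963961461
19466.015625,0.000556651025345347
19638.28125,0.000497563266012801
19810.546875,0.000539442508938982
19982.8125,0.000497192252260105
20155.078125,0.000420524857067512
20327.34375,0.000454281358509393
20499.609375,0.000599728660019967
20671.875,0.000671318635372774
20844.140625,0.000620597632238339
21016.40625,0.000538989725680578
21188.671875,0.00067421587973596
21360.9375,0.000649921597032738
21533.203125,0.000582523315287529
21705.46875,0.000550263768547717
21877.734375,0.000506693317388458
22050,0.000348661742093354
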