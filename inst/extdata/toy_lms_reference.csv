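"sex","axis","index_value","L","M","S"
"F","age",0,1,49.1,0.036
"F","age",30.4375,1,53.7381391970389,0.0361538461538462
"F","age",60.875,1,56.3780205156567,0.0363076923076923
"F","age",91.3125,1,58.5726740531486,0.0364615384615385
"F","age",121.75,1,60.5204383215011,0.0366153846153846
"F","age",152.1875,1,62.3030503994626,0.0367692307692308
"F","age",182.625,1,63.9642188533191,0.0369230769230769
"F","age",213.0625,1,65.5307544092791,0.0370769230769231
"F","age",243.5,1,67.0205885961209,0.0372307692307692
"F","age",273.9375,1,68.446455529942,0.0373846153846154
"F","age",304.375,1,69.8178067742954,0.0375384615384615
"F","age",334.8125,1,71.1418997913609,0.0376923076923077
"F","age",365.25,1,72.4244594799425,0.0378461538461538
"F","age",395.6875,1,73.6701018796687,0.038
"F","age",426.125,1,74.8826172519345,0.0381538461538461
"F","age",456.5625,1,76.0651659055959,0.0383076923076923
"F","age",487,1,77.2204176749326,0.0384615384615385
"F","age",517.4375,1,78.3506537635211,0.0386153846153846
"F","age",547.875,1,79.4578427189183,0.0387692307692308
"F","age",578.3125,1,80.5436981770277,0.0389230769230769
"F","age",608.75,1,81.6097234768195,0.0390769230769231
"F","age",639.1875,1,82.6572466358491,0.0392307692307692
"F","age",669.625,1,83.687448127471,0.0393846153846154
"F","age",700.0625,1,84.7013831999761,0.0395384615384615
"F","age",730.5,1,85.7,0.0396923076923077
"F","age",760.9375,1,86.6841544303022,0.0398461538461538
"F","age",791.375,1,87.6546224369823,0.04
"M","age",0,1,49.9,0.036
"M","age",30.4375,1,54.6395192887775,0.0361538461538462
"M","age",60.875,1,57.3371029312995,0.0363076923076923
"M","age",91.3125,1,59.5797270379169,0.0364615384615385
"M","age",121.75,1,61.5700653886378,0.0366153846153846
"M","age",152.1875,1,63.3916416650246,0.0367692307692308
"M","age",182.625,1,65.0891198118616,0.0369230769230769
"M","age",213.0625,1,66.6898965821595,0.0370769230769231
"M","age",243.5,1,68.2122954506809,0.0372307692307692
"M","age",273.9375,1,69.6693288748588,0.0373846153846154
"M","age",304.375,1,71.0706550097991,0.0375384615384615
"M","age",334.8125,1,72.4236899507349,0.0376923076923077
"M","age",365.25,1,73.7342837308702,0.0378461538461538
"M","age",395.6875,1,75.0071532868746,0.038
"M","age",426.125,1,76.2461717273867,0.0381538461538461
"M","age",456.5625,1,77.4545684390516,0.0383076923076923
"M","age",487,1,78.6350716131825,0.0384615384615385
"M","age",517.4375,1,79.7900123157292,0.0386153846153846
"M","age",547.875,1,80.9214021226105,0.0387692307692308
"M","age",578.3125,1,82.0309921262523,0.0389230769230769
"M","age",608.75,1,83.1203185254931,0.0390769230769231
"M","age",639.1875,1,84.1907383655944,0.0392307692307692
"M","age",669.625,1,85.2434579226069,0.0393846153846154
"M","age",700.0625,1,86.2795555103581,0.0395384615384615
"M","age",730.5,1,87.3,0.0396923076923077
"M","age",760.9375,1,88.3056660025492,0.0398461538461538
"M","age",791.375,1,89.2973464246759,0.04
"F","length",30,-0.35,1.05277614749674,0.081
"F","length",32,-0.35,1.22084901554464,0.0812
"F","length",34,-0.35,1.40309433673614,0.0814
"F","length",36,-0.35,1.59976796670735,0.0816
"F","length",38,-0.35,1.8111153495871,0.0818
"F","length",40,-0.35,2.03737248750733,0.082
"F","length",42,-0.35,2.27876677420053,0.0822
"F","length",44,-0.35,2.53551771751215,0.0824
"F","length",46,-0.35,2.80783757016324,0.0826
"F","length",48,-0.35,3.09593188401446,0.0828
"F","length",50,-0.35,3.4,0.083
"F","length",52,-0.35,3.72023548354167,0.0832
"F","length",54,-0.35,4.05682651342822,0.0834
"F","length",56,-0.35,4.40995623071554,0.0836
"F","length",58,-0.35,4.77980305307304,0.0838
"F","length",60,-0.35,5.16654095909957,0.084
"F","length",62,-0.35,5.57033974640536,0.0842
"F","length",64,-0.35,5.99136526666728,0.0844
"F","length",66,-0.35,6.42977964038207,0.0846
"F","length",68,-0.35,6.88574145364585,0.0848
"F","length",70,-0.35,7.35940593895888,0.085
"F","length",72,-0.35,7.85092514178043,0.0852
"F","length",74,-0.35,8.36044807432895,0.0854
"F","length",76,-0.35,8.88812085792875,0.0856
"F","length",78,-0.35,9.43408685504029,0.0858
"F","length",80,-0.35,9.99848679197181,0.086
"F","length",82,-0.35,10.5814588731502,0.0862
"F","length",84,-0.35,11.183138887727,0.0864
"F","length",86,-0.35,11.8036603092062,0.0866
"F","length",88,-0.35,12.4431543887061,0.0868
"F","length",90,-0.35,13.1017502423977,0.087
"F","length",92,-0.35,13.7795749336084,0.0872
"F","length",94,-0.35,14.4767535500258,0.0874
"F","length",96,-0.35,15.1934092763936,0.0876
"F","length",98,-0.35,15.9296634630539,0.0878
"F","length",100,-0.35,16.6856356906517,0.088
"F","length",102,-0.35,17.4614438312931,0.0882
"F","length",104,-0.35,18.2572041064153,0.0884
"F","length",106,-0.35,19.0730311416078,0.0886
"F","length",108,-0.35,19.9090380186001,0.0888
"F","length",110,-0.35,20.7653363246118,0.089
"F","length",112,-0.35,21.6420361992468,0.0892
"F","length",114,-0.35,22.5392463790944,0.0894
"F","length",116,-0.35,23.4570742401887,0.0896
"F","length",118,-0.35,24.3956258384656,0.0898
"F","length",120,-0.35,25.3550059483429,0.09
"M","length",30,-0.35,1.08374015183488,0.077
"M","length",32,-0.35,1.25675633953125,0.0772
"M","length",34,-0.35,1.44436181722838,0.0774
"M","length",36,-0.35,1.64681996572815,0.0776
"M","length",38,-0.35,1.86438344810437,0.0778
"M","length",40,-0.35,2.09729520772813,0.078
"M","length",42,-0.35,2.3457893263829,0.0782
"M","length",44,-0.35,2.61009176802722,0.0784
"M","length",46,-0.35,2.89042102810922,0.0786
"M","length",48,-0.35,3.18698870413253,0.0788
"M","length",50,-0.35,3.5,0.079
"M","length",52,-0.35,3.82965417423407,0.0792
"M","length",54,-0.35,4.17614494029376,0.0794
"M","length",56,-0.35,4.53966082573659,0.0796
"M","length",58,-0.35,4.92038549581049,0.0798
"M","length",60,-0.35,5.31849804613191,0.08
"M","length",62,-0.35,5.73417326835846,0.0802
"M","length",64,-0.35,6.16758189215749,0.0804
"M","length",66,-0.35,6.61889080627566,0.0806
"M","length",68,-0.35,7.08826326110603,0.0808
"M","length",70,-0.35,7.57585905481061,0.081
"M","length",72,-0.35,8.08183470477397,0.0812
"M","length",74,-0.35,8.60634360592686,0.0814
"M","length",76,-0.35,9.14953617727959,0.0816
"M","length",78,-0.35,9.71155999783559,0.0818
"M","length",80,-0.35,10.2925599329122,0.082
"M","length",82,-0.35,10.8926782517723,0.0822
"M","length",84,-0.35,11.512054737366,0.0824
"M","length",86,-0.35,12.1508267888887,0.0826
"M","length",88,-0.35,12.8091295177856,0.0828
"M","length",90,-0.35,13.4870958377623,0.083
"M","length",92,-0.35,14.1848565493028,0.0832
"M","length",94,-0.35,14.9025404191442,0.0834
"M","length",96,-0.35,15.6402742551111,0.0836
"M","length",98,-0.35,16.3981829766731,0.0838
"M","length",100,-0.35,17.1763896815533,0.084
"M","length",102,-0.35,17.9750157086841,0.0842
"M","length",104,-0.35,18.7941806977804,0.0844
"M","length",106,-0.35,19.6340026457727,0.0846
"M","length",108,-0.35,20.4945979603236,0.0848
"M","length",110,-0.35,21.3760815106298,0.085
"M","length",112,-0.35,22.2785666756953,0.0852
"M","length",114,-0.35,23.2021653902442,0.0854
"M","length",116,-0.35,24.1469881884296,0.0856
"M","length",118,-0.35,25.1131442454793,0.0858
"M","length",120,-0.35,26.1007414174118,0.086
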