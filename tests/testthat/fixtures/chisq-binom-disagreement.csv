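"a","b","chisq_p","binom_p"
0,4,0.0455002638963585,0.125
4,0,0.0455002638963585,0.125
0,5,0.0253473186774683,0.0625
5,0,0.0253473186774683,0.0625
1,7,0.0338948535246893,0.0703125
7,1,0.0338948535246893,0.0703125
2,9,0.0348084788118671,0.0654296875
9,2,0.0348084788118671,0.0654296875
3,11,0.0325094446457196,0.057373046875
11,3,0.0325094446457196,0.057373046875
4,12,0.0455002638963585,0.076812744140625
12,4,0.0455002638963585,0.076812744140625
5,14,0.0389474557420256,0.063568115234375
14,5,0.0389474557420256,0.063568115234375
6,15,0.0495346134356268,0.0783538818359376
15,6,0.0495346134356268,0.0783538818359376
6,16,0.0330062576612324,0.0524787902832032
16,6,0.0330062576612324,0.0524787902832032
7,17,0.0412268333371636,0.0639146566390992
17,7,0.0412268333371636,0.0639146566390992
8,18,0.0498602037569071,0.075518697500229
18,8,0.0498602037569071,0.075518697500229
8,19,0.0342640077348691,0.0522389858961105
19,8,0.0342640077348691,0.0522389858961105
9,20,0.0410872245278213,0.0614283457398414
20,9,0.0410872245278213,0.0614283457398414
10,21,0.048193488293191,0.0707555459812283
21,10,0.048193488293191,0.0707555459812283
10,22,0.0338948535246893,0.0501024597324431
22,10,0.0338948535246893,0.0501024597324431
11,23,0.0395917632366904,0.0576126729138197
23,11,0.0395917632366904,0.0576126729138197
12,24,0.0455002638963585,0.0652453352231534
24,12,0.0455002638963585,0.0652453352231534
13,26,0.0373729883406514,0.0532519140979277
26,13,0.0373729883406514,0.0532519140979277
14,27,0.0423302291213607,0.0595838880180964
27,14,0.0423302291213607,0.0595838880180964
15,28,0.0474253855087411,0.0659940344557982
28,15,0.0474253855087411,0.0659940344557982
16,30,0.0389999530124456,0.0540760318588696
30,16,0.0389999530124456,0.0540760318588696
17,31,0.0433081428107919,0.0594633752537703
31,17,0.0433081428107919,0.0594633752537703
18,32,0.0477148802373513,0.0649086470722723
32,18,0.0477148802373513,0.0649086470722723
19,34,0.0393595088882497,0.0534388105377112
34,19,0.0393595088882497,0.0534388105377112
20,35,0.0431144467830754,0.0580641467924093
35,20,0.0431144467830754,0.0580641467924093
21,36,0.0469447269784817,0.0627366803558286
36,21,0.0469447269784817,0.0627366803558286
22,38,0.0388671038124172,0.0518938959289215
38,22,0.0388671038124172,0.0518938959289215
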