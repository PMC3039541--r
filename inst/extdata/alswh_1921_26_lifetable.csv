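interval_start,interval_end,L,D,W,P_star,CP_star
0,1,12424,135,0,0.981,0.981
1,2,12289,181,0,0.979,0.960
2,3,12108,195,0,0.977,0.938
3,4,11912,185,0,0.975,0.914
4,5,11727,237,0,0.973,0.890
5,6,11490,226,0,0.971,0.864
6,7,11264,282,0,0.968,0.836
7,8,10981,359,0,0.964,0.806
8,9,10623,379,0,0.961,0.774
9,10,10244,361,0,0.956,0.740
10,11,9882,422,0,0.951,0.704
11,12,9460,398,707,0.945,0.665
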