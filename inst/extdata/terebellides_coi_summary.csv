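species,n_specimens,removed,orig_length,pruned_length,n_haplotypes,intra_min,intra_max,inter_min_lo,inter_min_hi,nearest,inter_max_lo,inter_max_hi,farthest
1,63,,658,555,12,0,1.9,15.6,17.7,7,17.4,20.3,8
2,32,,658,569,25,0,2.4,13.9,16.0,3,19.6,21.5,21
3,50,,658,615,44,0,2.3,13.9,16.0,2,20.1,22.4,21
4,14,,658,615,7,0,1.0,9.9,10.7,26,20.9,22.7,10
5,19,,658,600,10,0,1.1,12.3,14.0,16,19.6,21.6,15
6,33,1314_6,658,609,10,0,0.8,8.8,10.8,7,19.2,20.4,27
7,12,,658,627,8,0,0.6,8.8,10.8,6,19.2,20.9,4
8,40,1203_8,658,612,33,0,3.1,10.5,12.8,7,19.1,21.5,15
9,2,,649,603,2,0.2,0.2,11.2,12.1,7,20.5,21.9,4
10,12,,658,593,4,0,1.9,11.5,12.9,11,20.9,22.7,4
11,5,,630,615,4,0,1.1,11.5,12.9,10,19.5,19.7,26
12,23,,658,606,16,0,1.3,8.2,9.7,13,19.1,20.5,2
13,26,1959_13,658,597,14,0,1.9,8.2,9.7,12,19.5,21.3,15
14,18,,658,615,5,0,0.3,16.0,17.4,1,20.1,21.1,24
15,15,,658,567,4,0,0.5,17.2,18.6,6,19.5,21.8,16
16,55,2325_16,658,579,48,0,2.4,12.3,14.0,5,19.5,21.8,15
17,1,,NA,NA,1,NA,NA,14.6,15.6,6,20.6,21.4,20
18,3,,627,624,3,0.5,0.6,13.0,14.3,10,20.7,21.4,4
19,1,,NA,NA,1,NA,NA,12.1,12.5,10,19.6,20.8,3
20/28,7,,630,621,2,0,3.4,12.1,13.2,21,20.4,22.0,22
21,18,,658,585,2,0,0.3,12.0,13.2,20/28,20.1,22.4,3
22,1,,NA,NA,1,NA,NA,13.1,13.6,25,20.4,22.0,20/28
23,1,,NA,NA,1,NA,NA,17.4,18.9,16,22.9,22.9,24
24,5,,618,510,2,0,0.02,16.0,17.1,25,22.9,22.9,23
25,4,,624,567,2,0,0.8,13.1,13.6,22,20.7,21.7,23
26,1,,NA,NA,1,NA,NA,9.9,10.7,4,22.1,22.1,23
27,1,,NA,NA,1,NA,NA,11.1,12.3,4,20.7,21.8,10
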