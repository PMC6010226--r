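species,n_specimens,removed,orig_length,pruned_length,n_haplotypes,intra_min,intra_max,inter_min_lo,inter_min_hi,nearest,inter_max_lo,inter_max_hi,farthest
1,63,"856,858,1941,1955,2860,2789,2909",316,274,18,0,2.6,13.2,19.9,26,24.7,28.9,15
2,28,,291,257,8,0,1.7,3.9,6.7,3,26.9,31.2,25
3,55,,303,NA,8,0,3.4,3.9,6.7,2,30.7,31.8,23
4,13,,369,NA,1,0,0,0.56,0.85,26,32.3,33.7,15
5,18,,343,NA,4,0,1.5,1.8,3.2,16,28.5,31.9,21
6,25,,335,268,8,0,2.8,4.4,9.2,10,23.6,30.3,14
7,6,,322,NA,4,0,2.2,6.2,10.5,8,25.0,29.7,14
8,29,2896,327,292,5,0,1.2,6.2,10.5,7,29.6,33.0,25
9,2,,317,NA,1,0,0,6.7,10.7,8,26.3,30.4,14
10,7,,326,295,1,0,0.33,4.9,6.6,12,26.2,28.5,27
11,3,,350,323,2,0,0.31,9.8,12.4,12,30.2,32.9,4
12,17,2818,368,347,10,0,1.7,2.6,4.2,13,26.7,30.6,14
13,25,,357,288,3,0,0.64,2.6,4.2,12,28.1,31.6,14
14,19,"2477,2479,2852",361,332,6,0,1.5,9.4,13.9,5,30.6,35.3,15
15,16,,305,273,1,0,0,16.9,18.4,2,30.6,35.3,14
16,50,,348,NA,4,0,0.87,1.8,3.2,5,28.9,32.2,21
17,1,,315,NA,1,NA,NA,14.4,17.1,1,27.2,29.4,21
18,2,,344,NA,1,0,0,8.5,8.9,10,24.2,26.9,14
19,1,,312,NA,1,NA,NA,6.4,11.9,8,23.5,27.5,14
20/28,7,,410,NA,1,0,0,3.0,3.3,21,30.2,31.9,15
21,2,,419,391,1,0,0,3.0,3.3,20/28,32.1,33.4,15
22,1,,303,NA,1,NA,NA,19.7,22.0,24,30.0,31.1,21
23,1,,305,NA,1,NA,NA,8.8,9.7,10,24.3,28.0,14
24,4,,324,223,1,0,0,9.9,9.9,25,30.2,33.4,21
25,3,,309,NA,1,0,0,9.9,9.9,24,32.6,34.4,14
26,3,,365,184,1,0,0,0.56,0.85,4,22.3,33.9,15
27,1,,375,NA,1,NA,NA,1.6,1.6,4,32.3,33.8,15
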