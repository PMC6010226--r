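clade,n_specimens,coi,its2,coi_and_its2,rdna16s,rdna28s,concat
1,82,63,63,44,3,5,5
2,36,32,28,24,3,4,4
3,57,50,55,48,4,5,5
4,14,14,13,13,4,4,4
5,19,19,18,18,4,4,4
6,36,33,25,22,2,4,4
7,12,12,6,6,4,5,5
8,41,40,29,28,3,3,3
9,3,2,2,1,2,2,2
10,12,12,7,7,3,3,3
11,5,5,3,3,3,3,3
12,23,23,17,17,3,6,6
13,27,26,25,24,3,5,5
14,20,18,19,17,3,4,4
15,18,15,16,13,3,4,4
16,62,55,50,43,6,6,8
17,1,1,1,1,1,1,1
18,3,3,2,2,2,2,2
19,1,1,1,1,1,1,1
20,2,2,2,2,2,2,2
21,18,18,2,2,1,1,1
22,1,1,1,1,1,1,1
23,1,1,1,1,1,1,1
24,6,5,4,3,4,3,4
25,4,4,3,3,2,2,2
26,3,1,3,1,2,2,2
27,1,1,1,1,1,1,1
28,5,5,5,5,4,2,4
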