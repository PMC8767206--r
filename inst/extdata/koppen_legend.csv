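code,label
1,Af
2,Am
3,Aw
4,BWh
5,BWk
6,BSh
7,BSk
8,Csa
9,Csb
10,Csc
11,Cwa
12,Cwb
13,Cwc
14,Cfa
15,Cfb
16,Cfc
17,Dsa
18,Dsb
19,Dsc
20,Dsd
21,Dwa
22,Dwb
23,Dwc
24,Dwd
25,Dfa
26,Dfb
27,Dfc
28,Dfd
29,ET
30,EF
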