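channel,region
1,rDLPFC
2,rDLPFC
3,rDLPFC
4,rSFC
5,rSFC
6,lSFC
7,lSFC
8,lDLPFC
9,lDLPFC
10,lDLPFC
11,rDLPFC
12,rDLPFC
13,rDLPFC
14,rSFC
15,rSFC
16,lSFC
17,lSFC
18,lSFC
19,lDLPFC
20,lDLPFC
21,lDLPFC
22,rVLPFC
23,rVLPFC
24,rDLPFC
25,rDLPFC
26,mPFC
27,mPFC
28,lDLPFC
29,lDLPFC
30,lVLPFC
31,lVLPFC
32,rSTC
33,rSTC
34,rVLPFC
35,rVLPFC
36,mPFC
37,mPFC
38,mPFC
39,lVLPFC
40,lVLPFC
41,lSTC
42,lSTC
43,rSTC
44,rVLPFC
45,rVLPFC
46,rVLPFC
47,mPFC
48,mPFC
49,lVLPFC
50,lVLPFC
51,lVLPFC
52,lSTC
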