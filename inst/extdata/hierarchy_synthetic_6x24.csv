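child,parent
11,1
12,1
13,1
14,1
21,2
22,2
23,2
24,2
31,3
32,3
33,3
34,3
41,4
42,4
43,4
44,4
51,5
52,5
53,5
54,5
61,6
62,6
63,6
64,6
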