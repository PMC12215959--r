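"bin_index","r_div","g_div","b_div","group"
1,0,0,0,"black"
2,0,0,1,"blue"
3,0,0,2,"blue"
4,0,0,3,"blue"
5,0,1,0,"green"
6,0,1,1,"other"
7,0,1,2,"blue"
8,0,1,3,"blue"
9,0,2,0,"green"
10,0,2,1,"green"
11,0,2,2,"other"
12,0,2,3,"blue"
13,0,3,0,"green"
14,0,3,1,"green"
15,0,3,2,"green"
16,0,3,3,"other"
17,1,0,0,"other"
18,1,0,1,"other"
19,1,0,2,"blue"
20,1,0,3,"blue"
21,1,1,0,"yellow"
22,1,1,1,"grey"
23,1,1,2,"blue"
24,1,1,3,"blue"
25,1,2,0,"green"
26,1,2,1,"green"
27,1,2,2,"other"
28,1,2,3,"blue"
29,1,3,0,"green"
30,1,3,1,"green"
31,1,3,2,"green"
32,1,3,3,"other"
33,2,0,0,"other"
34,2,0,1,"other"
35,2,0,2,"other"
36,2,0,3,"blue"
37,2,1,0,"other"
38,2,1,1,"other"
39,2,1,2,"other"
40,2,1,3,"blue"
41,2,2,0,"yellow"
42,2,2,1,"yellow"
43,2,2,2,"grey"
44,2,2,3,"blue"
45,2,3,0,"green"
46,2,3,1,"green"
47,2,3,2,"green"
48,2,3,3,"other"
49,3,0,0,"other"
50,3,0,1,"other"
51,3,0,2,"other"
52,3,0,3,"other"
53,3,1,0,"other"
54,3,1,1,"other"
55,3,1,2,"other"
56,3,1,3,"other"
57,3,2,0,"other"
58,3,2,1,"other"
59,3,2,2,"other"
60,3,2,3,"other"
61,3,3,0,"yellow"
62,3,3,1,"yellow"
63,3,3,2,"yellow"
64,3,3,3,"grey"
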