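time,status
0.3,1
0.3,0
4.0,0
5.0,1
5.6,1
6.2,1
6.3,1
6.6,1
6.8,1
7.4,0
7.5,1
8.4,1
8.4,1
10.3,1
11.0,1
11.8,1
12.2,1
12.3,1
13.5,1
14.4,1
14.4,1
14.8,1
15.5,0
15.7,1
16.2,1
16.3,1
16.5,1
16.8,1
17.2,1
17.3,1
17.5,1
17.9,1
19.8,1
20.4,1
20.9,1
21.0,1
21.0,1
21.1,1
23.0,1
23.4,0
23.6,1
24.0,1
24.0,1
27.9,1
28.2,1
29.1,1
30,1
31,1
31,1
32,1
35,1
35,1
37,0
37,0
37,0
38,1
38,0
38,0
39,0
39,0
40,1
40,0
40,0
41,1
41,1
41,0
42,1
43,0
43,0
43,0
44,1
45,0
45,0
46,0
46,0
47,0
48,1
49,0
51,1
51,1
51,0
52,1
54,1
55,0
56,1
57,0
58,0
59,0
60,1
60,0
60,0
61,0
62,0
65,0
65,0
67,0
67,0
68,0
69,0
78,1
80,1
83,0
88,0
89,1
90,1
93,0
96,0
103,0
105,0
109,0
109,0
111,0
115,0
117,0
125,0
126,1
127,0
129,0
129,0
139,0
154,0
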