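node_id,network
1,VisII
2,Mot
3,MF
4,DMN
5,MF
6,DMN
7,VisI
8,Mot
9,VisII
10,DMN
11,DMN
12,MF
13,CBL
14,CBL
15,DMN
16,VisI
17,CBL
18,CBL
19,VisII
20,MF
21,FP
22,FP
23,VisII
24,MF
25,VisI
26,VAs
27,DMN
28,Mot
29,Mot
30,SAL
31,VisII
32,VAs
33,DMN
34,SAL
35,CBL
36,VisI
37,VAs
38,Mot
39,Mot
40,CBL
41,SC
42,Mot
43,MF
44,DMN
45,CBL
46,SC
47,CBL
48,SC
49,SAL
50,VisII
51,Mot
52,VAs
53,CBL
54,Mot
55,SAL
56,SAL
57,Mot
58,SC
59,FP
60,FP
61,CBL
62,VisI
63,SC
64,FP
65,SAL
66,SAL
67,MF
68,VisII
69,FP
70,VAs
71,MF
72,FP
73,SAL
74,FP
75,VisII
76,CBL
77,VisI
78,VisI
79,CBL
80,Mot
81,CBL
82,MF
83,DMN
84,Mot
85,VAs
86,SC
87,CBL
88,VAs
89,DMN
90,SAL
91,VAs
92,SAL
93,DMN
94,CBL
95,FP
96,FP
97,VisII
98,VisI
99,FP
100,SAL
101,CBL
102,CBL
103,DMN
104,CBL
105,FP
106,SAL
107,SAL
108,FP
109,FP
110,SAL
111,MF
112,SAL
113,VisII
114,VisII
115,MF
116,VAs
117,MF
118,Mot
119,SAL
120,Mot
121,CBL
122,SAL
123,VisII
124,VisII
125,CBL
126,SAL
127,SC
128,VisII
129,SC
130,VAs
131,CBL
132,VisI
133,MF
134,VisI
135,MF
136,VAs
137,FP
138,CBL
139,SAL
140,VisII
141,CBL
142,DMN
143,VAs
144,MF
145,FP
146,CBL
147,SAL
148,CBL
149,MF
150,FP
151,MF
152,SAL
153,MF
154,SC
155,VisII
156,CBL
157,SC
158,FP
159,VisI
160,Mot
161,VisI
162,SAL
163,VisI
164,CBL
165,MF
166,CBL
167,CBL
168,SAL
169,MF
170,SAL
171,SAL
172,SC
173,CBL
174,VisII
175,SC
176,Mot
177,SC
178,CBL
179,SC
180,VAs
181,Mot
182,SAL
183,SC
184,SAL
185,DMN
186,FP
187,MF
188,SAL
189,VisI
190,DMN
191,FP
192,VisI
193,FP
194,Mot
195,FP
196,FP
197,VisII
198,CBL
199,DMN
200,Mot
201,SC
202,DMN
203,VisI
204,SC
205,DMN
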