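state_id,dw,ui_low,ui_high
1,0.012,0.001,0.054
2,0.087,0.022,0.202
3,0.11,0.034,0.228
4,0.065,0.013,0.169
5,0.057,0.011,0.152
6,0.148,0.059,0.266
7,0.238,0.126,0.352
8,0.085,0.022,0.197
9,0.022,0.002,0.083
10,0.15,0.059,0.271
11,0.049,0.008,0.138
12,0.392,0.272,0.5
13,0.059,0.012,0.164
14,0.154,0.059,0.272
15,0.032,0.004,0.109
16,0.292,0.177,0.404
17,0.39,0.272,0.496
18,0.166,0.07,0.29
19,0.29,0.168,0.394
20,0.568,0.462,0.69
21,0.344,0.223,0.445
22,0.303,0.185,0.407
23,0.068,0.015,0.172
24,0.032,0.004,0.108
25,0.051,0.009,0.144
26,0.154,0.064,0.27
27,0.174,0.074,0.293
28,0.016,0.001,0.067
29,0.052,0.009,0.148
30,0.069,0.014,0.175
31,0.146,0.055,0.271
32,0.028,0.003,0.098
33,0.042,0.006,0.123
34,0.097,0.028,0.213
35,0.272,0.153,0.377
36,0.288,0.172,0.402
37,0.081,0.019,0.189
38,0.049,0.009,0.144
39,0.043,0.007,0.128
40,0.571,0.459,0.694
41,0.072,0.016,0.178
42,0.21,0.099,0.327
43,0.136,0.05,0.26
44,0.05,0.009,0.141
45,0.17,0.074,0.282
46,0.022,0.002,0.084
47,0.016,0.001,0.065
48,0.013,0.001,0.059
49,0.011,0.001,0.053
50,0.062,0.012,0.162
51,0.022,0.002,0.084
52,0.045,0.007,0.128
53,0.221,0.105,0.34
54,0.017,0.001,0.069
55,0.175,0.074,0.294
56,0.265,0.142,0.379
57,0.027,0.003,0.096
58,0.132,0.045,0.254
59,0.243,0.126,0.359
60,0.534,0.426,0.649
61,0.109,0.034,0.227
62,0.205,0.093,0.33
63,0.124,0.042,0.242
64,0.315,0.195,0.418
65,0.689,0.578,0.81
66,0.57,0.467,0.687
67,0.425,0.305,0.528
68,0.025,0.002,0.092
69,0.333,0.209,0.436
70,0.559,0.448,0.682
71,0.033,0.004,0.111
72,0.127,0.045,0.247
73,0.23,0.115,0.349
74,0.286,0.169,0.396
75,0.028,0.003,0.098
76,0.07,0.016,0.173
77,0.132,0.047,0.247
78,0.279,0.166,0.386
79,0.474,0.361,0.585
80,0.266,0.144,0.379
81,0.613,0.502,0.729
82,0.24,0.127,0.355
83,0.534,0.422,0.652
84,0.428,0.318,0.528
85,0.699,0.579,0.827
86,0.024,0.002,0.091
87,0.113,0.035,0.233
88,0.49,0.375,0.603
89,0.067,0.015,0.171
90,0.509,0.404,0.617
91,0.607,0.497,0.731
92,0.506,0.398,0.616
93,0.035,0.005,0.109
94,0.69,0.583,0.818
95,0.458,0.341,0.569
96,0.072,0.017,0.176
97,0.048,0.008,0.139
98,0.019,0.002,0.074
99,0.196,0.09,0.315
100,0.015,0.001,0.063
101,0.056,0.011,0.157
102,0.084,0.022,0.195
103,0.085,0.023,0.196
104,0.189,0.085,0.307
105,0.021,0.002,0.079
106,0.053,0.009,0.147
107,0.219,0.108,0.338
108,0.205,0.096,0.329
109,0.164,0.066,0.279
110,0.032,0.004,0.107
111,0.058,0.011,0.153
112,0.29,0.172,0.402
113,0.201,0.096,0.32
114,0.298,0.173,0.408
115,0.008,0,0.041
116,0.023,0.002,0.087
117,0.232,0.123,0.346
118,0.194,0.087,0.313
119,0.032,0.004,0.106
120,0.009,0,0.045
121,0.026,0.003,0.093
122,0.081,0.021,0.192
123,0.141,0.053,0.258
124,0.151,0.059,0.269
125,0.197,0.089,0.313
126,0.207,0.099,0.326
127,0.024,0.003,0.089
128,0.064,0.013,0.162
129,0.133,0.047,0.254
130,0.119,0.039,0.235
131,0.031,0.004,0.102
132,0.111,0.035,0.226
133,0.147,0.057,0.269
134,0.025,0.002,0.088
135,0.088,0.023,0.196
136,0.147,0.054,0.264
137,0.335,0.214,0.436
138,0.184,0.08,0.305
139,0.133,0.05,0.255
140,0.048,0.008,0.138
141,0.399,0.27,0.501
142,0.03,0.003,0.107
143,0.105,0.033,0.221
144,0.334,0.222,0.432
145,0.005,0,0.027
146,0.053,0.01,0.145
147,0.146,0.057,0.266
148,0.008,0,0.038
149,0.009,0,0.044
150,0.031,0.004,0.103
151,0.034,0.005,0.114
152,0.131,0.046,0.251
153,0.628,0.52,0.751
154,0.053,0.01,0.142
155,0.192,0.086,0.313
156,0.641,0.536,0.763
157,0.022,0.002,0.082
158,0.007,0,0.035
159,0.05,0.009,0.146
160,0.079,0.018,0.186
161,0.021,0.002,0.077
162,0.016,0.001,0.07
163,0.041,0.007,0.124
164,0.168,0.068,0.295
165,0.041,0.006,0.128
166,0.07,0.014,0.179
167,0.252,0.139,0.359
168,0.432,0.311,0.539
169,0.211,0.102,0.323
170,0.09,0.024,0.203
171,0.012,0.001,0.054
172,0.05,0.008,0.138
173,0.078,0.02,0.188
174,0.074,0.017,0.181
175,0.013,0.001,0.057
176,0.062,0.013,0.174
177,0.032,0.004,0.108
178,0.009,0,0.047
179,0.009,0,0.045
180,0.021,0.002,0.081
181,0.038,0.005,0.118
182,0.089,0.023,0.199
183,0.167,0.071,0.287
184,0.068,0.016,0.168
185,0.044,0.007,0.131
186,0.053,0.009,0.142
187,0.142,0.052,0.259
188,0.274,0.155,0.383
189,0.074,0.018,0.183
190,0.053,0.01,0.144
191,0.039,0.006,0.121
192,0.102,0.029,0.219
194,0.049,0.009,0.143
195,0.039,0.005,0.122
196,0.05,0.008,0.141
197,0.005,0,0.029
198,0.024,0.002,0.088
199,0.019,0.002,0.074
200,0.547,0.429,0.653
201,0.103,0.031,0.216
202,0.019,0.002,0.076
203,0.05,0.008,0.14
204,0.019,0.002,0.074
205,0.069,0.016,0.176
206,0.297,0.177,0.403
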