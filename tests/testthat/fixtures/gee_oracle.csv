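"id","t","x1","x2","y"
1,1,0,-0.097,6
1,2,0,-0.123,2
2,1,0,0.867,0
3,1,1,-1.058,8
4,1,0,0.143,1
4,2,1,-0.008,1
4,3,1,1.099,3
4,4,1,1.745,5
5,1,0,-0.051,0
5,2,0,-0.916,0
5,3,1,-0.565,1
6,1,0,1.482,1
7,1,1,-1.073,2
8,1,0,1.528,5
8,2,0,-1.754,6
8,3,1,-0.233,6
8,4,0,-1.067,7
9,1,0,0.926,3
10,1,1,0.821,1
10,2,0,-1.07,0
11,1,0,0.022,2
11,2,0,-0.217,1
12,1,0,-0.531,0
12,2,0,-2.705,0
12,3,1,-1.538,2
13,1,0,0.587,0
14,1,1,0.208,0
14,2,0,-0.861,1
14,3,0,2.26,0
15,1,1,-1.397,4
15,2,0,-1.58,1
15,3,1,-0.088,2
15,4,1,-1.181,2
16,1,0,2.261,2
17,1,1,0.222,3
17,2,0,0.163,2
18,1,1,-0.346,2
18,2,0,2.213,0
18,3,1,-1.77,2
18,4,0,1.073,1
19,1,0,0.632,5
19,2,1,-0.297,0
20,1,0,0.639,0
20,2,0,-0.882,3
21,1,0,0.334,3
21,2,1,0.531,5
22,1,0,-1.329,6
22,2,0,0.256,5
22,3,0,0.984,5
22,4,1,-0.604,16
23,1,0,-0.378,1
23,2,1,-1.539,1
24,1,1,2.44,2
24,2,0,-1.665,1
25,1,0,0.374,1
25,2,1,1.374,0
25,3,1,-0.266,0
25,4,0,1.777,0
26,1,0,-0.874,3
27,1,0,2.01,2
28,1,1,0.589,3
28,2,0,0.094,3
28,3,1,1.299,6
29,1,0,1.348,4
29,2,1,0.261,2
29,3,0,1.413,3
30,1,0,-0.266,6
31,1,1,-0.301,2
31,2,1,0.086,5
32,1,1,0.073,1
33,1,0,0.755,0
33,2,0,-0.762,1
33,3,0,0.933,1
33,4,0,0.528,0
34,1,1,-1.482,4
34,2,1,0.47,2
34,3,1,0.902,1
34,4,0,0.2,1
35,1,0,0.492,0
35,2,1,1.355,0
35,3,1,-1.949,0
35,4,0,0.355,0
36,1,0,-1.63,7
36,2,0,-1.04,4
36,3,1,-0.497,15
36,4,1,0.506,5
37,1,0,-0.199,2
37,2,0,0.338,0
37,3,0,-0.31,1
37,4,0,-0.933,1
38,1,0,-1.128,1
38,2,0,1.112,1
38,3,1,1.253,3
38,4,0,0.71,0
39,1,1,1.206,0
39,2,0,2.293,1
39,3,0,-1.593,4
40,1,0,0.166,2
40,2,0,0.698,1
41,1,0,-0.234,2
41,2,0,-0.062,2
41,3,1,0.858,2
41,4,1,-0.251,4
42,1,0,-1.467,1
42,2,1,2.445,3
42,3,1,0.914,2
42,4,0,2.205,1
43,1,1,-0.478,1
43,2,0,2.166,2
43,3,0,-0.697,1
44,1,1,0.32,0
44,2,1,1.383,0
44,3,0,1.371,0
45,1,1,0.108,2
46,1,0,-0.062,0
46,2,1,-0.689,0
46,3,0,1.177,0
46,4,0,-0.075,0
47,1,1,-1.105,1
47,2,0,0.722,0
48,1,0,-0.594,0
48,2,1,-0.201,1
48,3,0,0.545,1
48,4,1,0.849,1
49,1,0,-0.618,0
49,2,1,-0.324,2
49,3,1,-0.405,6
49,4,1,0.321,4
50,1,1,-2.065,1
50,2,0,-1.509,1
50,3,0,-0.66,0
51,1,0,-0.722,1
51,2,0,0.588,2
51,3,0,0.956,1
51,4,0,0.778,0
52,1,0,-0.319,0
53,1,0,-1.147,5
54,1,0,-0.043,2
54,2,1,-0.169,2
54,3,1,1.376,4
54,4,1,0.82,6
55,1,0,1.087,0
55,2,1,1.061,1
55,3,0,0.853,1
55,4,1,-0.164,2
56,1,0,-0.517,1
56,2,0,-1.742,2
56,3,0,-0.102,0
57,1,0,1.059,4
58,1,1,-1.344,2
58,2,1,0.995,0
59,1,1,-0.981,5
60,1,0,-0.028,4
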