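index,name,parent,side,group,mirror
1,nose,6,center,body,1
2,left_eye,1,left,body,3
3,right_eye,1,right,body,2
4,left_ear,2,left,body,5
5,right_ear,3,right,body,4
6,left_shoulder,12,left,body,7
7,right_shoulder,13,right,body,6
8,left_elbow,6,left,body,9
9,right_elbow,7,right,body,8
10,left_wrist,8,left,body,11
11,right_wrist,9,right,body,10
12,left_hip,0,left,body,13
13,right_hip,12,right,body,12
14,left_knee,12,left,body,15
15,right_knee,13,right,body,14
16,left_ankle,14,left,body,17
17,right_ankle,15,right,body,16
18,left_big_toe,16,left,body,21
19,left_small_toe,16,left,body,22
20,left_heel,16,left,body,23
21,right_big_toe,17,right,body,18
22,right_small_toe,17,right,body,19
23,right_heel,17,right,body,20
24,face_1,1,right,face,40
25,face_2,1,right,face,39
26,face_3,1,right,face,38
27,face_4,1,right,face,37
28,face_5,1,right,face,36
29,face_6,1,right,face,35
30,face_7,1,right,face,34
31,face_8,1,right,face,33
32,face_9,1,center,face,32
33,face_10,1,left,face,31
34,face_11,1,left,face,30
35,face_12,1,left,face,29
36,face_13,1,left,face,28
37,face_14,1,left,face,27
38,face_15,1,left,face,26
39,face_16,1,left,face,25
40,face_17,1,left,face,24
41,face_18,1,right,face,50
42,face_19,1,right,face,49
43,face_20,1,right,face,48
44,face_21,1,right,face,47
45,face_22,1,right,face,46
46,face_23,1,left,face,45
47,face_24,1,left,face,44
48,face_25,1,left,face,43
49,face_26,1,left,face,42
50,face_27,1,left,face,41
51,face_28,1,center,face,51
52,face_29,1,center,face,52
53,face_30,1,center,face,53
54,face_31,1,center,face,54
55,face_32,1,right,face,59
56,face_33,1,right,face,58
57,face_34,1,center,face,57
58,face_35,1,left,face,56
59,face_36,1,left,face,55
60,face_37,1,right,face,69
61,face_38,1,right,face,68
62,face_39,1,right,face,67
63,face_40,1,right,face,66
64,face_41,1,right,face,71
65,face_42,1,right,face,70
66,face_43,1,left,face,63
67,face_44,1,left,face,62
68,face_45,1,left,face,61
69,face_46,1,left,face,60
70,face_47,1,left,face,65
71,face_48,1,left,face,64
72,face_49,1,right,face,78
73,face_50,1,right,face,77
74,face_51,1,right,face,76
75,face_52,1,center,face,75
76,face_53,1,left,face,74
77,face_54,1,left,face,73
78,face_55,1,left,face,72
79,face_56,1,left,face,83
80,face_57,1,left,face,82
81,face_58,1,center,face,81
82,face_59,1,right,face,80
83,face_60,1,right,face,79
84,face_61,1,right,face,88
85,face_62,1,right,face,87
86,face_63,1,center,face,86
87,face_64,1,left,face,85
88,face_65,1,left,face,84
89,face_66,1,left,face,91
90,face_67,1,center,face,90
91,face_68,1,right,face,89
92,left_hand_root,10,left,hands,113
93,left_thumb1,92,left,hands,114
94,left_thumb2,93,left,hands,115
95,left_thumb3,94,left,hands,116
96,left_thumb4,95,left,hands,117
97,left_forefinger1,92,left,hands,118
98,left_forefinger2,97,left,hands,119
99,left_forefinger3,98,left,hands,120
100,left_forefinger4,99,left,hands,121
101,left_middle_finger1,92,left,hands,122
102,left_middle_finger2,101,left,hands,123
103,left_middle_finger3,102,left,hands,124
104,left_middle_finger4,103,left,hands,125
105,left_ring_finger1,92,left,hands,126
106,left_ring_finger2,105,left,hands,127
107,left_ring_finger3,106,left,hands,128
108,left_ring_finger4,107,left,hands,129
109,left_pinky_finger1,92,left,hands,130
110,left_pinky_finger2,109,left,hands,131
111,left_pinky_finger3,110,left,hands,132
112,left_pinky_finger4,111,left,hands,133
113,right_hand_root,11,right,hands,92
114,right_thumb1,113,right,hands,93
115,right_thumb2,114,right,hands,94
116,right_thumb3,115,right,hands,95
117,right_thumb4,116,right,hands,96
118,right_forefinger1,113,right,hands,97
119,right_forefinger2,118,right,hands,98
120,right_forefinger3,119,right,hands,99
121,right_forefinger4,120,right,hands,100
122,right_middle_finger1,113,right,hands,101
123,right_middle_finger2,122,right,hands,102
124,right_middle_finger3,123,right,hands,103
125,right_middle_finger4,124,right,hands,104
126,right_ring_finger1,113,right,hands,105
127,right_ring_finger2,126,right,hands,106
128,right_ring_finger3,127,right,hands,107
129,right_ring_finger4,128,right,hands,108
130,right_pinky_finger1,113,right,hands,109
131,right_pinky_finger2,130,right,hands,110
132,right_pinky_finger3,131,right,hands,111
133,right_pinky_finger4,132,right,hands,112
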