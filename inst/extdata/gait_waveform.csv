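stance_pct,axial_force_bw,flexion_deg
0,0.4,5
5,1.0,8
10,1.8,12
15,2.3,16
20,2.5,18
25,2.4,17
30,2.2,15
35,2.0,12
40,1.9,10
45,1.9,8
50,2.0,7
55,2.1,7
60,2.3,8
65,2.5,10
70,2.6,13
75,2.5,17
80,2.2,22
85,1.7,28
90,1.1,34
95,0.6,38
100,0.2,40
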