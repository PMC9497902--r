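treatment,X1,X2,X3,X4,X5,c1,c2,c3,c4,c5
1,3.16,1.78,0.26,19.50,75,0,0,0,0,0
2,3.16,1.78,0.26,22.50,75,0,0,0,2,0
3,4.20,1.18,0.40,18.00,90,1,-1,1,-1,1
4,3.16,1.78,0.26,16.50,75,0,0,0,-2,0
5,2.11,2.38,0.12,21.00,90,-1,1,-1,1,1
6,3.16,1.78,0.26,19.50,75,0,0,0,0,0
7,2.11,2.38,0.40,21.00,60,-1,1,1,1,-1
8,1.07,1.78,0.26,19.50,75,-2,0,0,0,0
9,3.16,1.78,0.26,19.50,105,0,0,0,0,2
10,3.16,1.78,0.26,19.50,45,0,0,0,0,-2
11,3.16,1.78,0.26,19.50,75,0,0,0,0,0
12,2.11,1.18,0.40,21.00,90,-1,-1,1,1,1
13,4.20,2.38,0.12,21.00,60,1,1,-1,1,-1
14,4.20,2.38,0.40,18.00,60,1,1,1,-1,-1
15,4.20,1.18,0.40,21.00,60,1,-1,1,1,-1
16,2.11,1.18,0.12,18.00,90,-1,-1,-1,-1,1
17,3.16,2.93,0.26,19.50,75,0,2,0,0,0
18,4.20,1.18,0.12,21.00,90,1,-1,-1,1,1
19,2.11,1.18,0.12,21.00,60,-1,-1,-1,1,-1
20,4.20,2.38,0.40,21.00,90,1,1,1,1,1
21,2.11,1.18,0.40,18.00,60,-1,-1,1,-1,-1
22,4.20,1.18,0.12,18.00,60,1,-1,-1,-1,-1
23,3.16,1.78,0.53,19.50,75,0,0,2,0,0
24,5.16,1.78,0.26,19.50,75,2,0,0,0,0
25,2.11,2.38,0.40,18.00,90,-1,1,1,-1,1
26,3.16,1.78,0.26,19.50,75,0,0,0,0,0
27,4.20,2.38,0.12,18.00,90,1,1,-1,-1,1
28,3.16,1.78,0.26,19.50,75,0,0,0,0,0
29,3.16,1.78,0.26,19.50,75,0,0,0,0,0
30,2.11,2.38,0.12,18.00,60,-1,1,-1,-1,-1
31,3.16,1.78,0.00,19.50,75,0,0,-2,0,0
32,3.20,0.60,0.26,19.50,75,0,-2,0,0,0
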