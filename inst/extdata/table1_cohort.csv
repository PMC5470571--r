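id,age,tsi_months,completeness,ais,motor_site,sensory_site,lems,uems,pp,lt,scim
1,28.97,12.07,Complete,A,C5,C4,0,14,13,16,19
2,43.19,15.73,Complete,A,C6,C4,0,25,18,20,37
3,21.01,12.33,Complete,A,C6,C5,0,23,26,53,34
4,31.69,10.27,Complete,A,C6,C5,0,26,20,33,30
5,19.08,13.5,Complete,A,C6,C7,0,23,33,33,37
6,33.59,12.2,Complete,A,C7,C7,0,35,29,32,26
7,60.36,68.17,Complete,A,T1,T1,0,49,40,52,32
8,52.76,54.6,Complete,A,T3,T3,0,50,44,47,53
9,26.13,10.8,Complete,A,T4,T4,0,50,46,48,67
10,70.28,9.5,Complete,A,T7,T7,0,50,68,67,49
11,39.24,9.33,Complete,A,T7,T7,0,50,58,60,65
12,53.12,8.03,Complete,A,T9,T9,0,50,66,68,69
13,30.58,10.27,Complete,A,T10,T10,16,50,78,82,80
14,36.44,185.47,Complete,A,T12,T12,4,50,78,78,70
15,54.65,18.63,Incomplete,D,C3,C3,49,42,94,62,84
16,48.13,12.13,Incomplete,D,C5,C5,47,35,97,98,98
17,68.91,285,Incomplete,D,T1,C3,40,49,78,69,NA
18,43.01,186.77,Incomplete,B,C6,C4,0,25,32,77,29
19,51.99,9.7,Incomplete,C,C7,C5,12,32,44,67,31
20,23.67,12.2,Incomplete,D,T1,C6,19,48,37,72,70
21,31.26,12.3,Incomplete,B,T1,C7,0,48,46,68,38
22,71.74,11.9,Incomplete,D,T1,T2,41,48,41,112,36
23,72.56,11.97,Incomplete,E,T3,T3,50,50,112,112,97
24,31.29,12.33,Incomplete,B,T4,T4,0,50,46,74,54
25,28.9,22.83,Incomplete,B,T6,T6,0,50,52,77,66
26,53.11,11.97,Incomplete,D,T10,T10,48,50,90,90,100
27,68.84,12.17,Incomplete,B,T11,T11,32,49,74,92,42
28,32.49,10.77,Incomplete,B,T11,T11,0,50,72,78,66
29,44.82,13.4,Incomplete,D,L3,L4,45,50,106,106,100
30,68.21,12.07,Incomplete,D,S1,L3,50,50,102,107,100
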