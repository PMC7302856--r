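subject_id,gender,age,age_at_amputation,level,side,cause,pal,wear_cosmetic,wear_mechanical,wear_myoelectric,usage_score_printed,own_condition,own_hand_like,myoelectric_viewed
01,Male,57,20,Below elbow,Left,Trauma,0.57,5,0,0,2.99,cosmetic,1,0
02,Female,49,0,Below elbow,Left,Congenital,0.46,4,0,0,1.92,cosmetic,1,0
03,Male,59,40,Above elbow,Left,Trauma,0,0,0,0,-2.42,NA,NA,0
04,Female,52,0,Below elbow,Right,Congenital,0.15,5,1,0,1.00,cosmetic,1,0
05,Male,58,27,Above elbow,Left,Trauma,0.09,5,2,0,0.72,mechanical,0,0
06,Male,53,28,Below elbow,Left,Trauma,0.24,3,5,0,1.43,mechanical,0,0
07,Male,52,0,At wrist,Left,Congenital,0.04,0,3,0,-0.60,NA,NA,0
08,Male,41,27,Above elbow,Right,Trauma,0.09,2,1,0,-0.91,cosmetic,1,0
09,Male,48,17,Above elbow,Left,Trauma,0,2,2,0,-1.34,NA,NA,0
10,Female,25,0,At wrist,Right,Congenital,0,0,0,0,-2.42,cosmetic,1,0
11,Male,49,0,Above elbow,Left,Congenital,0.26,1,4,0,0.98,mechanical,1,0
12,Male,37,27,Above elbow,Left,Trauma,0.28,0,2,0,-0.01,NA,NA,0
13,Female,46,38,Below elbow,Left,Trauma,0,0,0,0,-2.42,cosmetic,1,0
14,Female,28,0,At wrist,Left,Congenital,0,0,0,0,-2.42,NA,NA,0
15,Male,64,33,Below elbow,Right,Trauma,0.33,0,2,5,1.85,myoelectric,1,0
16,Male,38,0,Below elbow,Left,Congenital,0.39,5,0,0,2.14,cosmetic,1,0
17,Female,24,18,Below elbow,Right,Trauma,0,0,0,0,-2.42,cosmetic,1,0
18,Female,27,0,Below elbow,Left,Congenital,0.54,5,0,0,2.84,cosmetic,1,0
19,Male,49,37,Above elbow,Left,Trauma,0,1,0,0,-1.88,cosmetic,1,0
20,Male,60,0,At wrist,Left,Congenital,0.06,2,0,0,-1.05,cosmetic,1,0
21,Female,34,0,Below elbow,Right,Congenital,0.46,5,0,0,2.47,cosmetic,1,0
22,Female,36,0,Below elbow,Right,Congenital,0.57,5,0,0,2.99,cosmetic,1,0
23,Female,50,45,Above elbow,Left,Tumor,0,0,2,0,-1.34,mechanical,0,0
24,Female,41,0,Below elbow,Left,Congenital,0.54,0,0,5,2.84,myoelectric,1,1
25,Male,29,24,Through shoulder,Left,Trauma,0.09,0,0,2,-0.91,myoelectric,1,1
27,Male,25,0,Below elbow,Left,Congenital,0.59,1,0,5,3.08,myoelectric,1,1
28,Male,34,0,At wrist,Left,Congenital,0.11,0,0,3,-0.27,myoelectric,1,1
29,Male,25,18,At wrist,Left,Trauma,0,0,2,0,-1.34,NA,NA,1
30,Male,38,0,Below elbow,Left,Congenital,0,0,2,1,-1.34,myoelectric,1,0
31,Female,49,0,At wrist,Left,Congenital,0,1,0,0,-1.88,cosmetic,1,0
32,Male,45,20,Below elbow,Right,Trauma,0.09,2,0,0,-0.91,cosmetic,1,0
33,Male,32,31,Above elbow,Left,Trauma,0,0,2,0,-1.34,mechanical,0,0
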