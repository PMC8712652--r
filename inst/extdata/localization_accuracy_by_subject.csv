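contrast,intensity_db,s1,s2,s3,s4,s5,s6,s7,s8,s9,s10,s11,s12,s13,s14,s15,s16,s17,s18,s19,s20,s21,s22,s23,s24,s25
-90/0,48,80,70,70,75,70,60,75,80,70,60,75,65,75,75,80,65,70,75,70,65,60,75,70,70,65
0/+90,48,70,80,65,70,75,75,70,70,70,70,75,60,75,80,75,65,75,80,85,75,75,90,85,70,60
-90/+90,48,85,70,85,85,85,80,75,65,90,70,70,80,60,70,80,80,80,70,85,100,70,90,90,80,70
-90/0,58,65,85,75,65,65,75,65,85,85,70,70,70,70,75,70,70,70,85,70,80,75,80,80,70,70
0/+90,58,65,85,75,65,85,65,75,70,75,75,70,70,85,85,70,80,85,80,75,75,75,80,90,70,65
-90/+90,58,70,55,75,85,95,85,90,75,65,75,90,65,80,75,65,65,90,80,85,100,60,95,75,70,70
-30/0,48,65,70,80,65,80,70,80,60,80,75,60,70,65,70,65,25,65,40,65,70,70,65,70,70,70
0/+30,48,75,60,60,65,35,45,70,70,70,85,60,70,80,70,90,75,70,65,80,60,65,80,65,65,70
-30/+30,48,65,70,60,60,80,0,70,65,65,65,60,70,60,65,60,5,70,75,60,50,70,70,80,60,45
-30/0,58,65,60,65,75,80,75,80,60,65,65,65,60,65,70,65,70,75,75,65,60,75,70,65,70,75
0/+30,58,70,80,50,65,70,65,65,65,55,70,70,70,80,65,75,70,40,35,85,65,60,70,65,75,60
-30/+30,58,60,65,65,0,65,60,40,60,80,60,80,80,60,70,80,65,70,65,75,65,65,80,65,60,60
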