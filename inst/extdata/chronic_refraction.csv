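participant,sex,age,eye,naked_spherical,naked_cylinder,naked_axis,daily_spherical,daily_cylinder
1,male,19,R,-6.50,-0.75,10,-0.50,-0.50
1,male,19,L,-5.75,-1.25,160,-0.25,-0.75
2,male,23,R,-4.25,-2.75,0,-0.25,0
2,male,23,L,-5.00,-3.00,175,-0.50,0.25
3,male,19,R,-17.00,-1.00,175,-3.00,-1.00
3,male,19,L,NA,NA,NA,NA,NA
4,male,19,R,NA,NA,NA,NA,NA
4,male,19,L,-3.25,-1.25,0,-0.25,-0.50
5,female,19,R,-7.25,-2.25,0,0.25,0.25
5,female,19,L,-6.75,-1.00,170,0,0
6,male,32,R,-9.75,-1.25,5,0,-0.50
6,male,32,L,-10.50,-1.00,175,-0.75,-0.25
7,male,20,R,-3.00,-0.25,15,0,0.25
7,male,20,L,-2.00,-1.50,165,0.25,-0.25
8,male,19,R,-4.50,-2.75,170,0,-0.75
8,male,19,L,-3.75,-2.25,0,-0.50,-0.25
9,female,20,R,-5.25,-1.00,165,-0.25,-0.25
9,female,20,L,-5.00,-1.50,180,0,-0.50
10,male,19,R,-5.00,-2.00,5,0,0
10,male,19,L,-4.75,-1.75,165,0,0
11,male,19,R,-4.25,-1.75,5,-0.50,0
11,male,19,L,-4.25,-1.75,175,-0.75,-0.25
12,male,23,R,-5.50,-2.75,0,0,-0.75
12,male,23,L,-6.00,-3.25,170,-0.25,-0.25
13,female,19,R,-5.00,-1.75,25,0,-0.50
13,female,19,L,-5.00,-1.50,165,0,-0.25
14,female,19,R,NA,NA,NA,NA,NA
14,female,19,L,-7.25,-2.75,170,0.25,-1.00
15,female,18,R,-10.25,-3.25,0,-1.75,-0.25
15,female,18,L,-6.50,-3.75,0,-0.50,-0.75
16,male,22,R,-3.75,-1.00,0,-0.25,0
16,male,22,L,-4.00,-1.00,0,-0.25,0
17,male,19,R,-5.50,-0.75,5,-1.25,-0.25
17,male,19,L,-3.75,-1.25,165,-0.50,-0.50
18,female,19,R,-2.75,-0.75,5,-0.25,0
18,female,19,L,-3.00,-0.75,10,0.25,-0.75
19,male,19,R,-10.25,-2.25,170,-1.25,-0.25
19,male,19,L,-4.50,-2.00,10,0.50,-0.25
20,male,19,R,-0.75,-3.50,0,0,0
20,male,19,L,NA,NA,NA,NA,NA
21,male,22,R,-6.00,-2.50,170,-0.50,-0.75
21,male,22,L,-6.75,-1.50,170,-0.75,-0.50
22,female,20,R,-1.00,-0.75,170,-0.25,-0.75
22,female,20,L,0,-2.50,175,0,-0.50
23,female,19,R,NA,NA,NA,NA,NA
23,female,19,L,-3.50,-1.00,160,0,-1.00
24,male,26,R,-4.25,-3.75,0,0,0
24,male,26,L,NA,NA,NA,NA,NA
25,female,19,R,-2.75,-0.75,5,0,-0.25
25,female,19,L,-5.25,-1.00,170,-0.50,0
26,female,20,R,-4.25,-1.00,170,0.75,-1.00
26,female,20,L,NA,NA,NA,NA,NA
27,female,19,R,-5.00,-1.25,70,0,-0.75
27,female,19,L,-5.25,-1.00,95,-0.50,0.50
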