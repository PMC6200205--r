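#types
name,stage,rank
R1-6,photoreceptor,0
R7,photoreceptor,0
R8,photoreceptor,0
L1,lamina,1
L2,lamina,1
L3,lamina,1
L4,lamina,1
L5,lamina,1
C2,lamina,1
C3,lamina,1
T1,lamina,1
Mi1,medulla,2
Mi4,medulla,2
Mi9,medulla,2
Mi10,medulla,2
Tm1,medulla,3
Tm2,medulla,3
Tm3,medulla,3
Tm4,medulla,3
Tm9,medulla,3
Tm20,medulla,3
TmY-a,medulla,3
LC4,lobula,4
LC6,lobula,5
LC9,lobula,6
LC10,lobula,7
LC11,lobula,8
LC12,lobula,9
LC15,lobula,10
LC17,lobula,11
#edges
pre,post,rf_columns
R1-6,L1,1
R1-6,L2,1
R1-6,L3,1
R1-6,L4,1
R1-6,L5,1
R1-6,C2,1
R1-6,C3,1
R1-6,T1,1
R7,Mi4,1
R7,Tm20,1
R8,Mi9,1
R8,Tm20,1
L1,Mi1,1
L1,Mi4,3
L1,Mi9,3
L1,Tm3,3
L2,Tm1,1
L2,Tm2,3
L2,Tm4,3
L3,Mi9,1
L3,Mi10,3
L3,Tm9,1
L4,Tm2,3
L5,Mi1,3
L5,Mi4,1
C2,Tm1,3
C3,Tm9,3
T1,Mi1,3
Mi1,Tm3,1
Mi4,TmY-a,3
Mi9,TmY-a,3
Mi10,Tm20,3
Mi10,LC12,3
Tm1,LC4,5
Tm1,LC11,3
Tm2,LC4,5
Tm2,LC6,3
Tm3,LC6,5
Tm3,LC9,3
Tm4,LC9,5
Tm4,LC10,3
Tm9,LC10,5
Tm9,LC11,5
Tm20,LC12,5
Tm20,LC15,3
TmY-a,LC15,5
TmY-a,LC17,5
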