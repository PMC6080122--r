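transition,vertex,reference_mgdl,cgm_mgdl
A-B_upper,1,0,50
A-B_upper,2,30,50
A-B_upper,3,140,170
A-B_upper,4,280,380
A-B_upper,5,430,550
A-B_lower,1,50,0
A-B_lower,2,50,30
A-B_lower,3,170,145
A-B_lower,4,385,300
A-B_lower,5,550,450
B-C_upper,1,0,60
B-C_upper,2,30,60
B-C_upper,3,50,80
B-C_upper,4,70,110
B-C_upper,5,260,550
B-C_lower,1,120,0
B-C_lower,2,120,30
B-C_lower,3,260,130
B-C_lower,4,550,250
C-D_upper,1,0,100
C-D_upper,2,25,100
C-D_upper,3,50,125
C-D_upper,4,80,215
C-D_upper,5,125,550
C-D_lower,1,250,0
C-D_lower,2,250,40
C-D_lower,3,550,150
D-E_upper,1,0,150
D-E_upper,2,35,155
D-E_upper,3,50,550
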