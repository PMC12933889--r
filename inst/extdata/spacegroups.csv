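symbol,op,r11,r12,r13,r21,r22,r23,r31,r32,r33,t1,t2,t3
P1,1,1,0,0,0,1,0,0,0,1,0,0,0
P2,1,1,0,0,0,1,0,0,0,1,0,0,0
P2,2,-1,0,0,0,1,0,0,0,-1,0,0,0
P21,1,1,0,0,0,1,0,0,0,1,0,0,0
P21,2,-1,0,0,0,1,0,0,0,-1,0,0.5,0
C2,1,1,0,0,0,1,0,0,0,1,0,0,0
C2,2,-1,0,0,0,1,0,0,0,-1,0,0,0
C2,3,1,0,0,0,1,0,0,0,1,0.5,0.5,0
C2,4,-1,0,0,0,1,0,0,0,-1,0.5,0.5,0
P212121,1,1,0,0,0,1,0,0,0,1,0,0,0
P212121,2,-1,0,0,0,-1,0,0,0,1,0.5,0,0.5
P212121,3,-1,0,0,0,1,0,0,0,-1,0,0.5,0.5
P212121,4,1,0,0,0,-1,0,0,0,-1,0.5,0.5,0
P21212,1,1,0,0,0,1,0,0,0,1,0,0,0
P21212,2,-1,0,0,0,-1,0,0,0,1,0,0,0
P21212,3,-1,0,0,0,1,0,0,0,-1,0.5,0.5,0
P21212,4,1,0,0,0,-1,0,0,0,-1,0.5,0.5,0
P43212,1,1,0,0,0,1,0,0,0,1,0,0,0
P43212,2,-1,0,0,0,-1,0,0,0,1,0,0,0.5
P43212,3,0,-1,0,1,0,0,0,0,1,0.5,0.5,0.75
P43212,4,0,1,0,-1,0,0,0,0,1,0.5,0.5,0.25
P43212,5,-1,0,0,0,1,0,0,0,-1,0.5,0.5,0.75
P43212,6,1,0,0,0,-1,0,0,0,-1,0.5,0.5,0.25
P43212,7,0,1,0,1,0,0,0,0,-1,0,0,0
P43212,8,0,-1,0,-1,0,0,0,0,-1,0,0,0.5
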