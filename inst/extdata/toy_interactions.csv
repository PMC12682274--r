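group_id,actor_id,receiver_id,weight
g1,a1,a2,3
g1,a1,a3,2
g1,a2,a1,1
g1,a3,a4,1
g1,a4,a5,2
g2,b1,b2,5
g2,b1,b3,4
g2,b1,b4,3
g2,b1,b5,2
g2,b1,b6,1
g2,b2,b1,1
g2,b2,b3,2
g2,b2,b4,3
g2,b2,b5,4
g2,b2,b6,5
g2,b3,b1,2
g2,b3,b2,2
g2,b3,b4,3
g2,b3,b5,1
g2,b3,b6,4
g2,b4,b1,1
g2,b4,b2,1
g2,b4,b3,1
g2,b4,b5,2
g2,b4,b6,3
g2,b5,b1,1
g2,b5,b2,2
g2,b5,b3,1
g2,b5,b4,1
g3,c1,c2,6
g3,c1,c3,5
g3,c1,c4,3
g3,c1,c5,2
g3,c1,c6,1
g3,c1,c7,1
g3,c2,c1,4
g3,c2,c3,3
g3,c2,c4,2
g3,c2,c5,2
g3,c2,c6,1
g3,c3,c1,5
g3,c3,c2,1
g3,c3,c4,1
g3,c3,c5,3
g3,c3,c6,2
g3,c4,c1,2
g3,c4,c2,2
g3,c4,c3,4
g3,c4,c5,1
g3,c4,c7,3
g3,c5,c1,1
g3,c5,c2,3
g3,c5,c3,2
g3,c5,c4,5
g3,c5,c6,2
g3,c5,c7,1
g3,c6,c1,1
g3,c6,c2,1
g3,c6,c3,2
g3,c7,c1,2
g3,c7,c2,2
g3,c7,c3,2
g3,c7,c4,2
g3,c7,c5,2
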