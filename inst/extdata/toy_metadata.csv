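individual_id,group_id,species,sex,age,habitat
a1,g1,bonobo,female,12,zoo
a2,g1,bonobo,male,9,zoo
a3,g1,bonobo,female,21,zoo
a4,g1,bonobo,female,15,zoo
a5,g1,bonobo,male,7,zoo
b1,g2,chimpanzee,female,25,sanctuary
b2,g2,chimpanzee,male,18,sanctuary
b3,g2,chimpanzee,female,31,sanctuary
b4,g2,chimpanzee,female,12,sanctuary
b5,g2,chimpanzee,male,22,sanctuary
b6,g2,chimpanzee,female,8,sanctuary
c1,g3,bonobo,female,28,sanctuary
c2,g3,bonobo,male,14,sanctuary
c3,g3,bonobo,female,19,sanctuary
c4,g3,bonobo,female,33,sanctuary
c5,g3,bonobo,male,11,sanctuary
c6,g3,bonobo,female,6,sanctuary
c7,g3,bonobo,male,24,sanctuary
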