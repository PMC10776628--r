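word,gloss
árbol,tree
sol,sun
payaso,clown
puma,puma
avión,airplane
pelo,hair
pato,duck
casa,house
tiburón,shark
cama,bed
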