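hspb1
akt1
p70s6k
shp2
jnk2
ikba
gsk3b
p38mapk
nfkb
mp2k6
tor
mek1
erk1
rsk1
creb1
rs6
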