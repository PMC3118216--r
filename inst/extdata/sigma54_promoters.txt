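argT
astC
chaC
dcuD
ddpX
fdhF
glmY
glnA
glnH
glnK
gltI
hycA
hydA
hyfA
hypA
ibpB
kch
nac
norV
potF
prpB
pspA
pspG
puuP
rpoH
rtcB
rtcR
rutA
yaiS
ybhK
yeaG
yfhK
ygjG
yhdW
zraP
zraS
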