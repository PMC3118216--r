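dmsA
emrK
gadE
yca
spy
cydA
sucA
cpx
rdoA
ppiA
yqjA
acrD
ompC
mdtA
ftnB
yebE
ydeH
ycfS
efeU
yccA
aroG
ppiD
degP
ybaJ
cusR
dctA
frdA
dcuB
astC
kdpF
nrfA
nirB
hcp
napF
tppB
ompF
csgD
psiE
pstS
asr
phoH
phoB
phoA
phoE
mgtA
yrbL
mgrB
rstA
nagA
borD
hemL
ftsA
osmC
tnaA
torC
uhpT
zraS
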