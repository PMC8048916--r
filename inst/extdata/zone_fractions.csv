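region,rc_level,count_mean,count_sd,dorsal_pct,core_pct,ventral_pct
ALM,rostral,116,24,70,23,7
ALM,intermediate,62,12,87,8,5
ALM,caudal,30,7,76,11,13
MOs,rostral,125,11,24,57,19
MOs,intermediate,80,22,40,42,18
MOs,caudal,41,10,39,36,25
PL,rostral,171,74,25,51,24
PL,intermediate,91,36,20,55,25
PL,caudal,44,26,30,41,29
MOp,rostral,90,14,62,31,7
MOp,intermediate,60,15,81,13,6
MOp,caudal,27,5,79,13,8
ACA,rostral,74,3,10,47,43
ACA,intermediate,45,6,14,45,41
ACA,caudal,25,2,21,30,49
rRSP,rostral,117,47,17,76,7
rRSP,intermediate,88,39,17,73,10
rRSP,caudal,38,5,24,61,15
SSbfd,rostral,23,4,43,50,7
SSbfd,intermediate,16,5,64,30,6
SSbfd,caudal,9,2,65,25,10
iRSP,rostral,73,23,5,90,5
iRSP,intermediate,46,16,5,90,5
iRSP,caudal,29,10,5,90,5
AUDp,rostral,36,17,34,43,23
AUDp,intermediate,26,3,40,37,23
AUDp,caudal,11,5,39,34,27
VISp,rostral,44,17,23,51,26
VISp,intermediate,31,5,16,57,27
VISp,caudal,20,3,20,55,25
cRSP,rostral,32,8,6,80,14
cRSP,intermediate,36,10,4,82,14
cRSP,caudal,26,3,7,71,21
ENTl,rostral,91,45,11,31,58
ENTl,intermediate,78,42,19,19,62
ENTl,caudal,67,36,15,7,78
pSUB,rostral,51,13,9,65,26
pSUB,intermediate,52,15,10,68,22
pSUB,caudal,30,5,13,55,32
ENTm,rostral,110,16,16,40,44
ENTm,intermediate,59,20,13,44,43
ENTm,caudal,40,11,17,33,50
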