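patient,modality,scale,overlap,adjacent,isolated,jaccard
bvFTD1,flte,absolute,32,68,0,0.18
bvFTD2,flte,absolute,44,56,0,0.27
nfPPA1,flte,absolute,21,78,1,0.08
nfPPA2,flte,absolute,12,26,62,0.05
PSP1,flte,absolute,19,78,3,0.10
PSP2,flte,absolute,8,90,2,0.05
svFTD1,flte,absolute,76,24,0,0.00
svFTD2,flte,absolute,17,26,56,0.04
svFTD3,flte,absolute,40,60,0,0.24
bvFTD1,sd,absolute,32,68,0,0.20
bvFTD2,sd,absolute,55,45,0,0.36
nfPPA1,sd,absolute,44,54,3,0.21
nfPPA2,sd,absolute,27,32,41,0.12
PSP1,sd,absolute,23,76,0,0.14
PSP2,sd,absolute,15,80,5,0.09
svFTD1,sd,absolute,59,32,9,0.05
svFTD2,sd,absolute,83,16,1,0.28
svFTD3,sd,absolute,51,48,1,0.37
bvFTD1,flte,relative,10,86,4,0.04
bvFTD2,flte,relative,4,73,23,0.02
nfPPA1,flte,relative,22,75,2,0.06
nfPPA2,flte,relative,29,60,11,0.11
PSP1,flte,relative,22,77,2,0.09
PSP2,flte,relative,2,84,14,0.01
svFTD1,flte,relative,41,53,6,0.05
svFTD2,flte,relative,46,49,5,0.10
svFTD3,flte,relative,22,65,12,0.05
bvFTD1,sd,relative,19,75,6,0.12
bvFTD2,sd,relative,15,72,13,0.10
nfPPA1,sd,relative,43,56,1,0.21
nfPPA2,sd,relative,35,51,14,0.19
PSP1,sd,relative,25,74,0,0.15
PSP2,sd,relative,10,72,19,0.05
svFTD1,sd,relative,68,31,1,0.25
svFTD2,sd,relative,80,19,1,0.38
svFTD3,sd,relative,43,46,11,0.25
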