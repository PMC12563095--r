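descriptor,Molinspiration,Molsoft,SwissADME,Mcule,AdmetLab,pkSCM,Deep-PK,admetSAR,mean_printed
MW,329.33,329.12,329.33,329.32,329.12,329.33,329.33,329.33,329.28
TPSA,76.51,59.73,76.50,76.50,76.50,nd,76.50,76.50,74.11
MR,nd,nd,89.01,89.01,nd,nd,nd,nd,89.01
LogP,3.73,2.61,3.11,3.62,2.54,3.54,2.41,2.67,3.03
nRB,4,nd,4,4,4,4,4,4,4
nHA,6,5,6,7,6,6,6,6,6
nHD,2,2,2,2,2,2,2,2,2
nRings,nd,nd,nd,3,3,nd,nd,nd,3
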