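parameter,PreADMET,SwissADME,AdmetLab3,pkSCM,Deep-PK,admetSAR3,consensus_printed
caco2,moderate,nd,high,moderate,moderate,moderate,moderate
hia,high,low,high,high,high,high,high
mdck,low,nd,moderate,nd,high,low,low
pgp_substrate,nd,no,nd,yes,no,no,no
pgp_inhibitor,yes,nd,nd,yes,no,yes,yes
ppb,high,nd,high,nd,high,high,high
clearance,nd,nd,low,moderate,low,low,low
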