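parameter,PreADMET,TEST,AdmetLab3,pkSCM,Deep-PK,admetSAR3,consensus_printed
ames,positive,positive,positive,negative,positive,positive,positive
carcinogenicity,negative,nd,positive,nd,negative,negative,negative
herg,active,nd,inactive,inactive,inactive,inactive,inactive
hepatotoxicity,nd,nd,positive,positive,positive,positive,positive
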