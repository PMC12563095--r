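id,criteria_pct,violation_points,target
TKI.1,60,"Distribution, Overall Toxicity",Ret
TKI.2a,60,"Distribution, Overall Toxicity",VEGFR-2
TKI.2b,60,"Distribution, Overall Toxicity",VEGFR-2
TKI.4,80,Distribution,c-Met
TKI.6,60,"Distribution, Overall Toxicity",dual EGFR/HER2
TKI.8,60,"Distribution, Bioavailability",EGFR
TKI.14a,60,"Distribution, Overall Toxicity",EGFR
TKI.14b,60,"Distribution, Overall Toxicity",
TKI.16,80,Overall Toxicity,VEGFR-2
TKI.19,80,Distribution,VEGFR-2
TKI.20b,60,"Medicinal Chemsistry,Distribution",VEGFR-2/FGFR-1/PDGFR-β
TKI.21b,80,Distribution,EGFR
AIK.1,80,Overall Toxicity,BTK
DDK.8,80,Distribution,LRRK2
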