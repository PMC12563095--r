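druglikeness,med_chemistry,bioavailability,distribution,toxicity
AIK.1,TKI.16,TKI.16,TKI.16,TKI.19
TKI.19,DDK8,DDK.8,AIK.1,DDK8
DDK8,TKI.19,TKI.19,,TKI.4
TKI.21b,TKI.21b,TKI.21b,,TKI.21b
TKI.16,AIK.1,TKI.4,,TKI.8
TKI.4,TKI.4,AIK.1,,TKI.20b
TKI.20b,TKI.14b,TKI.14a,,TKI.18
TKI.1,TKI.8,TKI.14b,,TKI.13b
TKI.14b,TKI.6,TKI.6,,TKI.13a
TKI.14a,TKI.2a,TKI.1,,
TKI.2b,TKI.2b,TKI.20b,,
TKI.2a,TKI.14a,TKI.2a,,
TKI.8,TKI.1,TKI.2b,,
TKI.6,TKI.17,TKI.10,,
TKI.20a,TKI.11,TKI.5,,
TKI.10,TKI.15,TKI.21a,,
TKI.5,,TKI.9,,
TKI.9,,TKI.20a,,
TKI.21a,,AIK.3,,
TKI.17,,TKI.3,,
TKI.18,,TKI.7a,,
TKI.13a,,,,
TKI.13b,,,,
TKI.11,,,,
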