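# Curated SUBSET of the PAINS (pan-assay interference) catalog. The full
# published catalog has 480 family A/B/C patterns; this file carries
# hand-transcribed SMARTS for prominent PAINS chemotype classes and can be
# replaced by a full catalog file via the config
# (format: SMARTS <whitespace> pattern_id).
[#6]1(=[OX1])[#6]=[#6][#6](=[OX1])[#6]=[#6]1	quinone_para
[#6]1(=[OX1])[#6](=[OX1])[#6]=[#6][#6]=[#6]1	quinone_ortho
[OX2H]c1ccccc1[OX2H]	catechol
c[NX2]=[NX2]c	azo_aromatic
[OX2H]c1ccc(cc1)[CX3]=[NX2][NX3]	hzone_phenol
[#6X3]=[#6]1[#16X2][#6](=[SX1])[#7][#6]1=[OX1]	ene_rhodanine
[#6X3]=[#6]1[#6](=[OX1])[#7][#6](=[OX1])[#7][#6]1=[OX1]	ene_barbiturate
[OX1]=[#6]1[#6]=[#6][#16X2][#7]1	isothiazolone
[OX2H]c1ccc(cc1)[NX2]=[NX2]	azo_phenol
[NX3][NX2]=[CX3]1[#6](=[OX1])c2ccccc2[#6]1=[OX1]	hzone_indanedione
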