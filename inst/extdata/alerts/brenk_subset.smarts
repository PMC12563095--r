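# Curated SUBSET of the Brenk unwanted-functionality catalog (reactive,
# toxic or pharmacokinetically unfavourable groups). The full published
# catalog has 105 patterns; this file carries hand-transcribed SMARTS for
# the most common motifs and can be replaced by a full catalog file via
# the config (format: SMARTS <whitespace> pattern_id).
[NX3](=O)=O	nitro_group
[NX3+](=O)[O-]	nitro_group_charged
[CX3H1](=O)[#6]	aldehyde
[CX3](=[OX1])[F,Cl,Br,I]	acyl_halide
[CX4][Cl,Br,I]	alkyl_halide
[CX3]=[CX3][CX3]=[OX1]	michael_acceptor
[NX2]=[NX2]	azo_group
N=[N+]=[N-]	azide
[SX2][SX2]	disulfide
[O,N,S;r3]	three_membered_heterocycle
[NX3][NX3]	hydrazine
[CX3;!R]=[NX2;!R]	acyclic_imine
[NX2]=C=[OX1]	isocyanate
[NX2]=C=[SX1]	isothiocyanate
[OX2][OX2]	peroxide
S(=O)(=O)[F,Cl,Br,I]	sulfonyl_halide
[SX2H]	thiol
[CX3]=[NX2][OX2H]	oxime
[CX3]=[SX1]	thiocarbonyl
[NX4+]	quaternary_nitrogen
[F,Cl,Br,I]c1ccccn1	2_halo_pyridine
[CX2]#[CX2]	acetylene
C(=O)Oc1ccccc1	phenyl_ester
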