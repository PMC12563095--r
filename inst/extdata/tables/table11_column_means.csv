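mw_exp,tpsa_exp,mr_exp,logp_exp
467.46,96.66,132.43,3.69
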