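block,term,b,r,r2,rmse,mae,rmse_baseline,ci_low,ci_high
MW,constant,(Constant),0.159,-,-,-,-,-,-0.172
MW,slope,1.000,1.000,1.000,0.230,0.152,72.469,0.999,1.001
TPSA,constant,(Constant),1.057,-,-,-,-,-,-1.333
TPSA,slope,1.012,0.995,0.991,2.995,2.712,21.090,0.988,1.037
MR,constant,(Constant),12.326,-,-,-,-,-,2.058
MR,slope,0.917,0.950,0.902,7.249,5.521,21.919,0.840,0.994
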