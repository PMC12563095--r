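block,term,b,r,r2,rmse,mae,rmse_baseline,ci_low,ci_high
LogP_consensus,constant,(Constant),2.213,-,-,-,-,-,1.098
LogP_consensus,slope,0.481,0.645,0.417,1.142,0.892,1.430,0.199,0.763
LogP_molinsp_molsoft,constant,(Constant),1.658,-,-,-,-,-,0.615
LogP_molinsp_molsoft,slope,0.603,0.750,0.562,0.970,0.786,1.430,0.339,0.867
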