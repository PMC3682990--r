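glucose_mM,rate_pM_per_min,provenance
3,1,"Estimated anchor point added for fitting"
4,10,"Estimated anchor point added for fitting"
5,16,"Overnight fast, Polonsky et al. 1988; fasting glucose taken as 5 mM"
7,33,"24-h mixed diet, Polonsky et al. 1988; assumed 7 mM"
9,47,"Jones et al."
16.5,102,"Hyperglycemic clamp at 16.5 mM, Polonsky et al. 1988"
25,103,"Estimated anchor point added for fitting"
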