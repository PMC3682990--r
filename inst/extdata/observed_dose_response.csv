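glucose_mM,insulin_pM
5,57.0
7,167.4
16.5,567.4
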