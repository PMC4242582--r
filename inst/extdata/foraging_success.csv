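sex,pct_successful_pecks,n_pecks,pct_successful_probes,n_probes
male,67,425,33,120
female,13,42,87,124
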