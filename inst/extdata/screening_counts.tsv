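group	n_observed	n_tt4	n_tt8
non-irradiated	430	0	0
irradiated	2588	2	17
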