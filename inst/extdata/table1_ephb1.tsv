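snp	group	n_AA	n_Aa	n_aa
rs3732568	controls	693	165	10
rs3732568	cases	891	172	8
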