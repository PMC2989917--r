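snp	group	n_AA	n_Aa	n_aa
rs6852678	controls	39	28	9
rs6852678	cases	62	54	5
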