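snp	group	n_AA	n_Aa	n_aa
rs12765929_ERneg	controls	514	306	50
rs12765929_ERneg	cases	189	96	8
rs12765929_ERpos	controls	514	306	50
rs12765929_ERpos	cases	389	243	34
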