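# kozakscan 1.0.0
transcript_id	position_1based	codon	concentration	main_tic_start
synth_0001	50	CTG	10	107
synth_0002	36	CTG	10	80
synth_0003	55	CTG	10	139
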