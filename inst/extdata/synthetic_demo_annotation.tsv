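# kozakscan 1.0.0
transcript_id	main_tic_start_1based	cds_end_1based	gene
synth_0001	108	263	NA
synth_0002	81	209	NA
synth_0003	140	304	NA
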