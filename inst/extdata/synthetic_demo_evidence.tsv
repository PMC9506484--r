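# synthetic N-terminal peptide evidence for the demo cohort
peptide	transcript_id	acetylated	source
ATPHAII	synth_0001	TRUE	synthetic
MAAALRSE	synth_0002	FALSE	synthetic
AKSLREP	synth_0003	TRUE	synthetic
HKLRHT	synth_0003	TRUE	synthetic-decoy
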