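# kozakscan packaged default bits matrix
# positions 1-10: ten nucleotides 5' of the codon (left to right)
# positions 11-20: ten nucleotides 3' of the codon (left to right)
position	A	C	G	T
1	0.08	0.25	0.1	0.06
2	0.07	0.25	0.11	0.05
3	0.09	0.1	0.25	0.06
4	0.08	0.25	0.09	0.07
5	0.1	0.12	0.4	0.06
6	0.11	0.4	0.12	0.05
7	0.12	0.4	0.08	0.06
8	0.6	0.06	0.3	0.04
9	0.1	0.4	0.12	0.05
10	0.4	0.08	0.12	0.05
11	0.15	0.1	0.6	0.05
12	0.1	0.4	0.12	0.06
13	0.08	0.4	0.12	0.05
14	0.25	0.09	0.1	0.06
15	0.07	0.25	0.1	0.05
16	0.08	0.1	0.25	0.06
17	0.09	0.25	0.08	0.06
18	0.06	0.25	0.1	0.07
19	0.08	0.1	0.25	0.05
20	0.07	0.25	0.09	0.06
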