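>synth_0001
CCGCCATTCTGGCCTCGTAAGCCCTCCCTCAAGAATCTCCCGTGCAACACTGGCCACGCCCCACGCAATCATACCGGAAC
GGCGATCAAGCCAATTACGTGGCCACAATGGCCACGTCGCTAGCTACACGCCGAGAAAGATCAACCACAGTATTCCAGCT
CCTCGCAAGAGAACGTACTACAATTACTAGGCTACACTTTTACCTTGTTGTGCCGCGGATCCTATTAGCAGCCTACAAGT
CCTGCTTCGATTCGACTCTTTAATCCATCTTAGCAAGGACAGAGCGTT
>synth_0002
AATATGCACGTCGTGTCTCCTACGTCTCCGCCACACTGGCCGCGGCGCTACGTTCTGAAACGCACGATATCCGCGCCACA
ATGGGCACGCGGGGCGTTGAGTCGCGAGCTTTGGGTAATATCCATCGAATAGACTTCGAGTTCACCATTATTCGCGGTCG
CTGGGTGCACAGTCTTAGCCCACATAGACTGGGTTTCCCCGCTCTGTGAGCTTAACTGCTTCACATAGGAGCTA
>synth_0003
TTGTCATGGCGCTTTATCTAGTTTAGAGGTTGCGCGGCCACAAACTGCGCCACACTGGCCAAGTCGTTACGAGAGCCACC
GGCACCGGGCGGGAGTAACTGGAGATAAGGCATGTGGGTCGTATACTCTCGGCGTCACAATGGCCCAGTTCTTAGCAGTT
TACCGAATTGCCTTGATCACTTATAAACGTAGGACAAGATCGAATTCGACAAGTGCACGTCTGGCTGTCTCAAGATGTAC
TTCGGGAGTATGTAAAATGCCGATGCGCCGTTTCAACAGTCGGAGACACACAAGTTCCGGATGAGATCCGGGATAGGTAC
GGCTCAGCC
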