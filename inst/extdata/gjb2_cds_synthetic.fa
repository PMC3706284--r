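>GJB2_CDS_synthetic length=681 coord=c.1
GTGATGCGTACAGAACCCTCCTTCCGGAGTAGCAGGTCGTTCGTCGAGAAAGGGTGAATT
ATAGCTGCATACTATGGAGGCATCTCAATACAAGGTGACATGTATTTCGTAGTTAGTAGG
ACTCTAATATCTATGCTATCACCTCTCTATCTGCAACATGAAGCGTGTGAACTTAAGAAT
TAACTGAAGTCATGACCAACTACCCTTGCACTCGAGTCTTAAGATGAAGTCTGGCCGGCT
CGGTTCCCAACGACTTCGGATGCACATACGGTATGGTTTTCGTTGCTAGATTCTGGAAAT
AGGAGCGAACGTGAACACATCAACATGCGGCCTGACTAACACCGCGGTTTGCTATGGCAC
GGCTTTGCATCGGAGCTCGGCGCTTCCCCCCTGTCACAGCTGAGTGGGAACCATGGCCTA
ATCCGTTGTAATGCTGTTCGTTCGTTCAAAGCGCTCATGCACCCAGGTCATTGGATGCTT
GTGCGACTCTATAGATCCGTTTAGTAACGTTTGGCTTGTCGGACGTAATAATGACGCGAG
CGTTTCGCACATGGACCCGTTTCAGTGTGATGTGGGTCACTCGGACTAGCCCCACGACGG
CGAAGTATCCGCGATAGATTAGTTGAATCCATAGGGGCAATTCCCTGGGCAATGGGGCTC
TGATGATGTCAAACTGAAACA
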