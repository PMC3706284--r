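>MT12S_synthetic length=1021 offset=m.600
CGCTAACCGTTTGCAACTGACACAACAACGCCTCCCGCGTACTCCGTCGCTGACGATTAG
GAGATTCCTGAAAAAGCGCAGTTTGTATGGAGTGATACTCTATGTCACAGAAACTGTTTA
TTACATCATGCAATTACATTGCCACACTTAATCTTGGGACCGGTCGCTTTGTACTGTTGG
AATTAGCGTTGTTTCCGAACGGAGCTGGCGCATCGCCAGACACATACACCGGCGGTATTC
AGTCATCAATGCCATACCTAAGTCAAAGTTGCATTGACGTGTTAAAGAGAAGGGTTCTCC
TAGATGGTTATGACATTCCGTTTCAGGGTACTTAGATGCCACTCATGCAAATAACCTTCT
ATTGAGGCTCTTACGAATGCCATACAAAATACCGTAGCGGGGGACTAGCCATGTGCCACT
CCATCCAGCGAGTAACTGCCTAGTCCCTCACTTTCTTGACTTGCAGAACGCCACCTGGTT
ATTTGTAGATAGTCATCACTTTGGTCCTGTTTTGTCTCATAGGCTTATTCGGGTGACATG
GGAAGGGAGGCTTGACATATGTTCGACAGTCGCAGCTACACTAGACTTCTAAAATCTTCT
GGTACCGAATGGAAGACCTTGTAAAACTGCGTGGCCGTTTCGAACTGCTACGGGGTCAAT
GCTCGTAGGAACATACCATGGAGGTATTTGCTTCCGGAGAGGCGACCAACCGCTTCGGGT
TGGTTAGCGAGTGAGCAGCTAATCACTGATTCGAATGTTTTGAGCACGACGGCCGTTTTG
TGACGGACAAAGGAACCGGTCCTTATCACTATCGGGAGCCTTTTGTCTCCCACAGCAAAG
CTAAGAACCAATATAGGACAGGCTCAGCAGCTATAGTTCGGAGAAGGTCAAAAGCGAACT
AGCGAATCGAGCTATGGTTTTGTAATAGTCCATCCCCCCAAAATTTGATCACGTTACCGG
TTCCCAATTGTTTTATTCCCGCCCTCTATGATCTGCTTGGGTATTTTAACTACACAAACT
C
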