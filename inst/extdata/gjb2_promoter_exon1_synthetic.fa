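>GJB2_promoter_exon1_synthetic length=300
CTTTCCGCGCGGCTCCCTAATGGTCCCCGACTGATCCGGTTGGCGCTACGGCTTTACGGA
GGACTACTAATTTCCTGACTATTTGGAGTCCAACGAACTTTTGTACAGTTGAGGTGGCGA
GCTCTCCAAAAATCAACTCAGCCTCCCAATACATAGCCGCAGGTTATGACCGTCAGATGG
AATCTTTGCGTTTCTTGAAAGACTACTTTCGAATCGATTCAAACGTCTCTCCGCCTAGCA
GATTCCATCAGCCCAAAACTACTCGGAGTCAGGAATCCCTGAGGACTGGATCGCGGATGG
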