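>cons01_DNA-hAT-Ac#DNA/hAT-Ac
CTGGTGTTCACCGTTCACATAAGCCTGCAATTACGGACAGCCGTCTTAGGAGTTGGAATA
ATTGTCCGTTGAGTTGTAGAAATAGTCTACTCGAGAGTCGTGATACAAACAGCATCCATA
CACAGAGCCCTAATGGGAAGCTATGCTAGTTTCAGTAATAAGCACCAGTTCGTCTGTACG
ACTGACGGGAAAAAAATTCCCAGACATTACGCTTCTTCAAATCTACTCATAACTGCTACC
TATTAATCACTAATATTTGAAATGAGTACCAAAAGTGATCGGAGATCCCAGCCGTTCGCA
AGTGCACGACAAGTTAACGACGTCTTCCTAACTGATCCCCTGCCTTGTGTCTCGGAGCTG
GAGGGCAGTGGCCATGAAGAATAGGTCGCTGACAGCCCAG
>cons02_LINE-L2#LINE/L2
TCGCAAGGCGATATTCCTGAACGCTCATGCGAGGGCACCTATCATCTTTAGGTAGTTGGC
CAGTTTTGTATATATATGACGCCTCACTATCCTCGCACGCCTGTCATTGCAATCTAGTAC
TCTCGGAGAAGCTGGAGTCTCTTGAGAAGGTTACATAGTCGTGGCAGAGCTGAATTCACC
AACTCGTTGGGACCACAGTGGCAGTGCACCGGTTGCGTCGGTAAACAGCTTCTTTCCTAT
AAGGGAAGCTTAAGGCAGTGTGATCATTCAAGCTAATTGCAGATGTTAGACTATGAACCA
TGCAGAATATTCGTCACAAGTAGCAAAGGGTAGCTAGTAACATTTCTTTGTGTATTCAAG
GGTTGCTTCTGAAACTTGCCTCGACTAGCAGGTTTGAATACACAGTATCAATGTTTGTGT
CTTACAGAGATGATAAATGGATCCTGTTCG
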