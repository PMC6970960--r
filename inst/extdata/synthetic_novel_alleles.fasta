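>AS2UBAs1 synthetic novel UBA allele
CTGGGAATAGGCCTTCTACATTTCTTCTGGAACACCGCTCTGACCATGCGTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTTCT
GGTATCACCCTGGCTCCTACTACTACTACTACTACTGCTGCTGCTGCTGCTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTCGTCATGTTATC
GCTGCTGCTCGTTCTGCTGCAAAAGGTACCGTTGAAATCAAACAGATGATCTTCCATGAT
TGGACCACCATGTGGAAACTGATGCATAACGTTAACCAGAAAGGTGCACAGGCTGTTTGG
GTTGCTGTTGCACCTTCTCATAACATGCCTGTTTGCCATGCTGAATCTAAAGTGGCTGAA
GAAGTATCTGGAGCTGCAGCCGCTGCAGCCGCTGCAGCCGCT
>AS2UBAs2 synthetic novel UBA allele
CTGGGAATAGGCCTTCTACATTTCTTCTGGAACACCGCTCTGACCATGCGTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTTCT
GGTATCACCCTGGCTCCTGCTGCTGCTGCTGCTGCTACTACTACTACTACTACTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTCGTCATGTTATC
GCTGCTGCTCGTTCTGCTGCAAAAGGTACCGTTGAAATCAAACAGATGATCTTCCATGAT
TGGACCACCATGTGGAAACTGATGCATAACGTTAACCAGAAAGGTGCACAGGCTGTTTGG
GTTGCTGTTGCACCTTCTCATAACATGCCTGTTTGCCATGCTGAATCTAAAGTGGCTGAA
GAAGTATCTGGAGCTGCAGCCGCTGCAGCCGCTGCAGCCGCT
>AS5UBAs1 synthetic novel UBA allele
GGCATCTGCAGTAACCCACTTTCTTCTGGAACACCGCTCTGACCATGCGTGCTGCTGCTG
CTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTG
CTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTTCTG
GTATCACCCTGGCTCCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTACTACTA
CTACTACTACTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTCGTCATGTTATCG
CTGCTGCTCGTTCTGCTGCAAAAGGTACCGTTGAAATCAAACAGATGATCTTCCATGATT
GGACCACCATGTGGAAACTGATGCATAACGTTAACCAGAAAGGTGCACAGGCTGTTTGGG
TTGCTGTTGCACCTTCTCATAACATGCCTGTTTGCCATGCTGAATCTAAAGTGGCTGAAG
AAGTATCTGGAGCTGCAGCCGCTGCAGCCGCTGCAGCCGCT
>AS5UBAs2 synthetic novel UBA allele
GGCATCTGCAGTAACCCACTTTCTTCTGGAACACCGCTCTGACCATGCGTGCTGCTGCTG
CTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTG
CTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTTCTG
GTATCACCCTGGCTCCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTG
CTGCTGCTGCTACTACTACTACTACTACTGCTGCTGCTGCTGCTGCTCGTCATGTTATCG
CTGCTGCTCGTTCTGCTGCAAAAGGTACCGTTGAAATCAAACAGATGATCTTCCATGATT
GGACCACCATGTGGAAACTGATGCATAACGTTAACCAGAAAGGTGCACAGGCTGTTTGGG
TTGCTGTTGCACCTTCTCATAACATGCCTGTTTGCCATGCTGAATCTAAAGTGGCTGAAG
AAGTATCTGGAGCTGCAGCCGCTGCAGCCGCTGCAGCCGCT
>AS9UBAs2 synthetic novel UBA allele
CTGGGAATAGGCCTTCTACATTTCTTCTGGAACACCGCTCTGACCATGCGTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTTCT
GGTATCACCCTGGCTCCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTACTACTACTACTACTACTCGTCATGTTATC
GCTGCTGCTCGTTCTGCTGCAAAAGGTACCGTTGAAATCAAACAGATGATCTTCCATGAT
TGGACCACCATGTGGAAACTGATGCATAACGTTAACCAGAAAGGTGCACAGGCTGTTTGG
GTTGCTGTTGCACCTTCTCATAACATGCCTGTTTGCCATGCTGAATCTAAAGTGGCTGAA
GAAGTATCTGGAGCTGCAGCCGCTGCAGCCGCTGCAGCCGCT
>AS7UBAs1 synthetic novel UBA allele
CTGGGAATAGGCCTTCTACATTTCTTCTGGAACACCGCTCTGACCATGCGTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTACTACTACTACTACTACTTCT
GGTATCACCCTGGCTCCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCT
GCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTCGTCATGTTATC
GCTACTACTCGTTCTGCTGCAAAAGGTACCGTTGAAATCAAACAGATGATCTTCCATGAT
TGGACCACCATGTGGAAACTGATGCATAACGTTAACCAGAAAGGTGCACAGGCTGTTTGG
GTTGCTGTTGCACCTTCTCATAACATGCCTGTTTGCCATGCTGAATCTAAAGTGGCTGAA
GAAGTATCTGGAGCTGCAGCCGCTGCAGCCGCTGCAGCCGCT
>AS5DABs2 synthetic novel DAB allele
ATGTCGATGTCTATCTTCTGGATTGCGATGAATTCGGTGCCACCGCCATCGCTGCTGCTG
CTACTACTACTACTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTG
CTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTTACT
GCGTTTCTCAGGCACTGACTACTACTACTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTG
CTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGATGCAGGTGTTA
AAGCTGCTTACGCCCAGATGGCTGGTCAGCTGCATGTTAAAAACCCTTTCTGCCAGATGA
TGATCGCAGATCGTGAACAGTCTAACGGTCCTCAGCAGAACTTCGCTGTTGCATACGCTG
CTGTTGGTCCTCCTGTTAAATGCGTTATCCGTATGGTTTTCCTGGCCGCTCTGGCTAACG
GGGACTGGTACGCTGCAGCCGCTGCAGCCGCTGCAGCCGCT
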