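>ref16S_synthetic length=1542 gc=0.67 synthetic stand-in for the E. coli rrnB 16S gene; positions are used as the standard 16S numbering frame; seed=165420
GCTAGCAAAGCGGACGGTACCGGTGCGCGCGCGAGGCAGGCGGGCCACGCCTGTTGCCCG
CAGCAAGCGTCGTGGGAGACAGCGGATCATTCTGGTCCGGCCACCATTCAGACTGTTCGA
CCTCCCTGAATGGCATGCAGGACGACGTCTGGAACGGCGCCGCCTTGTTGGGAGATGGAC
TGGGGTTTCAGGCGATGAGACTGAATTCCCTGGGGCGGGCGCGCTCGGTCCTGTTTCGGC
CTCTCGCTAGAGCCATACTCGTGTGCGCTATTATCACCCGGAGTACATACCTGGTCTCGC
ATGAGTTGGCCTCGGCTGCGGCTCGCAATACAGCGTGCGATCCGGGTTCTACCCGACCGA
GCTAAATCTCGCGAGCATGACCCTCTGTGGACCCAAGTGCCGACGTCCCCTGGTCCCGGT
CATATGGCCCGCTCTAGGCCGTAGGGCCCGCCTCGCAAAGTACATGCAGGGCTCACGGGT
CCTTTTGGCGGGTGCACTGGCTGCCCTGCAGTCGGCGTGCGGGCTGCCGAAGCGAGGACT
CTGCCTCATCTCGTTCACACGGTTCGTGTACTAGCACCACGCAGTCCGGATAGCGATCCT
CCAGGGACGGGAACGTCCGCCGCACGAGTCAGACGCTAACCCGCTGCCACTAGTCCCGGA
GAACCGAGTGCCGCAGTCCTTCGGCCCGGTCGGTTCTAGCCCGTATGCCCATAACGATAG
AGGGGACCCCTGCGTGTGTATGCGCGACGAACCTGCCGCGAGTACCCAGCAAGCCAGAGC
ACCACCACGGCGCGAGGTGCAACGAGCATATTGCGGTATGAGCCTCAGCAGAACGCTAGT
AATGTAGGGCAAGCGGCCGGCGGTGCAACCCCCCTGCATCACCCCTGTGGGACTCGGCCG
AGTGTCGGAGGACCATGCGGGGGCCTACAGCCTAGGTGACAGCGTGTGGAACGCACCGCC
CTGGCGAGTGACCCAGACAACGCCGGCGGAGGGGGAGACCTCTCGGCACACGTCTGGCTG
GTCGGGGTATCCCAGTGATGCTACAACGGTTGAGGCGCGCCCCCTTCAGCCGGCTCATTC
CGGACGCCCACCACCGGCCCACCCCAGGTCACAGACGCCGCGCGACGCTCGCAGGGGCGC
TGTCGGGTTAACTCGCGGGAGGATGGCACAGGGGTACGAGCTCGCGCTCGGAGGGGGATC
AGTCCGCAGTCTGCCGTGGTATTTGCTGACGCGACCTGGGCCCGGCGTGCCGCGCGCGCT
GTCGAGTGTCGCTCGCGTTCCTAAGGCGGGAAGCCAGCTCCGGTGGTCCAGACATCCAGC
AAGGGGCCGGCCGGAATTTCGTGCCCGCCTAGGCCCCCCATCATAGATCCATTGCCCAAG
GGAAGAACGCGGCGTCGGCTCGGGGGCTCAGATACGATTATAGCGCAAGTGATGGTTCAG
AAACACCCGCTTGAAGTGAAGTCGGTGCCCCAAGTGAACAGAGCATGGGGGCCGCGACCG
GCACGCCCGCGGGAGGATGGCGGAACCAGCAAGCGTCCGGCG
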