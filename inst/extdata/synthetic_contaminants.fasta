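>mock_rRNA_LSU synthetic mock contaminant
GCTAGATCGCGGCTTTGCCCCCAGTGCACCGGGGCGTATAAGTAGAGGGCTATACACGAGACTTGAGACACTGGGCGCTT
GTCGGCCGCACACGCCAGGCCATCTTGGCCGACATGCCCGGAGTGGTACCCGGAGTGGTGTATCCGTGCAGCTAATCGGG
GTTGCAAAACTGGCACGCTCGCGGATATCTGTGTGTTATTCGGGCTCGCCGGATGCCCTGGAACGCCGCTATCTCCGGCT
TTTGCTCTGATCGTACAACGTAGCTCAAGCGAATTTCGGCTCAGTTTACGCAGATTCCATCACCAGACTCCCGGTGATAA
GTCAACGCCCCGTATCACCAAACGTCTGCATTCTACTTTTCTCGGACGCCCAGTAAGCACTCATCTCTCACTTGCTGACT
CTGCCCTGCCCCGACCGCCCGACGACTGCTCTCGAGCACCCAAAGGAGAGTTGCGCTGGCCGGAATACCTCTGTTGGTAC
ACCGGTGGCGCGCCAGAATGGGGGCCTGAGTCCCAGGCTCCGGAATCCCGTTGACCGACACATGCACCCCAAGCCCCCAA
GGATGGTATGTCAAACGTAAGTTCCCTCCACTAAGAACAATAGGGGGGCAGGAGTGTACGCTCCAAGTTAGCGGCACCAC
GCATGCTCGGCGGGACCGTGCAGAGTCCAGCCTAGAGAGATGTCCGCTCCAGAATTGGCTGCGCTTCCCCCCAGGCGCCC
TACGCCGGAGCTACGGCGACATCTCCCACCAGTTGCCGCCCCTTCCCTAGTCGATAAAAGAAAACTAGGCCGGCCCCGGC
TCTAGAAGGCAGATCCCCCTTCTGGTGAGCCTATAAGAGCTGATGACGAGCTGATGCAAGGTCGCCGCCTGCCCATCCTC
CCCTGCACGCGATAGTTCGTCCCCATGGAGAGATGCTCGTCCGACACGCCACGGCGGGGGAGGCGGATTGGACACACACG
GTGTCGAGACCTCCCAGCGGGGACATTAGGTCCGGCCCGCGAACAAGGCCCACTATCCCTGTGTGGCCCAATAGCATGGG
GAAGGACACGCCCGCGTTACGCGGGCACCTGGTGCGGAAGTGATGCCACTCTGCGGCCACGATGCAGGGGTCGAGTGATG
TGCCGCGCATCCCGGCGCATTTCATGGCACGTTAGCGAAGCCACGGGGACCCGCGGATCTCGCGCACACTTACCGCAGCG
>mock_tRNA_pool synthetic mock contaminant
CGTTCCCCGTAGCAAACGCCTAGTGCGATATGACTCTCGTAGGAAGGGACATCCCCATCTGAACTTGCAGCACCGTCGGT
ACGGTACCCAGAAGAGCTTAATTTTCGCCAAAGCCCTAACTTTTGTCACCCCATTGACTTCAATCCCTAAACGCGTAATT
GGCCTTATAGTCTGTGTCTCTGTATACATGCCCCATGATAGTATCCCCCCGATCATCCCCCTCCCTGTGTGCAAATTATG
TTTCCATCAGAGGCGCCAGTCGTTGGTGCGCGTGATATGCGCCCAATAGAGCTTACTGAATGCGCTCTACGCACAGGACA
ATTTCGGCGAGTTTAGTTCTTTTTGTCATCGCTACGTGCCGTTATTAGAAATGACAGGAGAAGTCAGTTAAGTCACTCAT
CAAGATATCGTTTCAATTTCTAACCAAATGGTTGGTCCACTGTCTATAAAAGCCACCCTAACAGTTATGCAGAATCTCCT
TTAATGACTCTGCTAGAGCCCTCCTGAGCGACCAAGATCATTCTCGGCCAGCCGTTATGTGGGACCATAATCCGGTACGA
AACGTGTCCCCCTAGGGGGTCATCATTTTTACATGCTCTTTTTAGTGATGTTATCGTACGGTACTCGGTGAAGTGTAGTA
TAACGCCTTGCGTGATAAGGATGACAGGAGTTTCTGGCAATACAGGTAGGCACAGCAAGCCCGCCTTACCTCCCCGTTTG
ACACGCTCTACTCCTCCGGATGGGTGGGCTGAGTCCTATTCGAGAGAGGAAGGGTTTACTTGCCACTAAGACTTTTCAAT
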