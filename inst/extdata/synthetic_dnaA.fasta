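>synthetic_dnaA_1
ATGTATTCGAAAGGCGGAGCGTACATTTATCATCGCTCAGCGGGCTCGAATCCCTGCACT
CATGAATGGGGCATCGCGTCGAAGTTGCCACCCACGCTCGGGGAAATTGAGATGCGCTTC
CTGAACTCCATTAGAGCGACATCCTACTTGCTCCCAACAACGGGTACTCCGCGCAGCTAT
TCTTGCACTGCAGCACAAGCTGAAAGTGCCCAACGTAGGATTGGAGGGCCAGAGTATCGG
GCGTTGATGCGAGTCCTACCCCGACTGCCGGTCCACTCGCTCGGTAATCCACTCAGTCAA
TACCGCTATTACCCAAATGGGCGTGGGGCCGCGTGTGCGCGGATGTACATCGTATCTAGT
ACCCAGCACAGTGTTGTCGACGTGCGATGTGCCCTGTGTATTGATAGAGTCCGTAGGAAA
GTATTACCACGACGTCACTGCCTGATGATGGGTGAGCTTTGTGTCGGCCCTCAGGACAAT
TTACATGCAGGTCATCTGTCGCACTATAGTTATACTAAGACGTTCCAGGCATCCAGGAAG
GCACCCGTTAACACGATGAGCGTTCTATGCTGGAAACAAGGTCGCACGGGCCTCCTGTTT
TTAACGGTTCAAAAGCAGATCGGATGTCTCAGTTCGGGATATTATCCACCGTTATTACTC
ATTGAGTCGCCGAGTTGCAAGTTGCTGGCTATTCAGGACCTTATCTTCGCTGCGCCCATA
GACCGAGACGTAAAGGTTTATTTTGCTAAAGACGAGCTCCAAAAGAGACACGAATCGGTA
CTAAAATTCCCTGTTAAGTCGCATGGTGCACGTCACGGATCACGATGGGGCGAATACTCT
CATCTCGTTAACGTCTGTCCCGGCCACAGTCGCGAGTTTAGGCTGTGGTCCTGCAGTAGT
CCCCGTAGTATTTTGTCGCTGAACGCCACGGGCAGGAAATTAGATTATATACTCTACCGT
ACGATTATGGCGCCCAACTTTTCATATATCTTCCCATCCTAA
>synthetic_dnaA_2
ATGCCCACTATTTGGATACTCAGGATGCGAAGCTGCCCTTGGATAACCCTCGCCGCGATG
TCCGGCAGTCTTTATTTCCTTGCCGTGGCCGCACATTGGGGACGCACTCGTTCATTACTA
TCTCCTGGATGTGGCTCGCAACCGACGATCAATAAGATCCACGCGGGTTCTCGCAGGGCT
GCCCCCATAATTGAGCTTTTACTCGAGGTCGCGTTGCAGAGGTCCGTGTTTTCAGTGCCA
AAGCAGTACCGGGTAATTTTCAGTCAACTCGAAGAGCATGTCCCCCTGCGAAGTGGATCA
CCTCTCTACGGCGTGGGACGAACCAACAATCGTGAATCCTTTCCCATGACGAGCGACTAC
ACCAATGACTTCGGATCGTTGACTCCTCCTGGAGATACGATTACAGGCTGCTTTCGGGAG
AATGCTTCCCCTGTGACCGCAGTGGGCTTCATGCGGCCTGGCCAAAGGCGAGGTATAGCA
AAGCCATTAATGCATAAATGGGGATATCTATCCAAACTGTGTACAGAACTTTCTAGGTTT
CTTCCAATGCCCACGAGCGCGTGTTGTCCCCGAATCAATAATGAAAAGTACGGAGAGGGG
CCCTCTTCGGCAGTCAATACAATCCGAGGGAGCGATTGCCTAGGAAATCGTCTGAGCAGT
TGTATCACGCACAATGGCCTCAACTATAGGAGCTTTACCGGAGTAAGGAAAATATTGTGC
ATTGGACTTTTGAACGACCATAGAGCGGCAGGAGTTATCCCCGGTGGCCGCCACGTGCAC
CCTGAAGGTCAGGCCCGGGAAGGAGCCATGTCAACCGTCTTGATGCGTAATCGCGTCGGT
TTCCTGTTGCCGATGCCTACGCGGGCTGCCTCTCTGATTCTGTGCGAGTCTGCAATTTAA
>synthetic_dnaA_3
ATGAGCATGTGGGTTGTGGTTTTGTACCATGCCGAGATAGGGTTGTTACAAAGGTTGCCG
CTCTTGCACCCTCACTTGTTGAGATGTTTTCGTTTGAGGAGGAGAATTAAGTCGAGCTGG
GGACTTGTTATTATAATCAGCGAGTCCAACACAGTTCGGCTGGGAAGAAAGCTCCCGTTG
CCCCGTGGTGATAGACAGGAATGGGATATAGTACGGTACCGGGCCCCAAAGGGTCCCTAC
CGGTATATTGAAGATAGAACCACTGGAAACTTTCTACCGGCTGATCAGTTTAGTATGACG
GGGAAAGTATCAATAATAGTATCGACGAACTCGTTATCGTGCTATCTCTACCTTAGTGAC
ACTCGGTTGACGCTATTCCCGCCCTGCGGCAGACCCCTCCGTAATGAGGGTAATGCCGGT
ACTGGTACGCCAATGCTAGAAATTTACACTACTCATAAAAGACCTGGGTTCCCCCCTACG
GCCGCTACCTTTATTCTGCATTACGGGCGCATGGTCACGTCCACAAGCGACGTGCGTCCC
CCTCGGCGAACCGCCCTGCTGGTGGACACGGCTTCATATACATTGCCTAAACTCGACGCG
TGTACGATCGTCTGCTGTGCCGGGCCGATTGTAACGCGTGCGTGGCTGCTCGGACAGAAT
ATCGAGAAATTAGCTATTTCTCAGCTCCTGCAGTGGTTCCCTTCGTCTACGTGGCCGCGC
GTGACGCTTCGCTTTCTCGATTACTTCTCCTGCTATCCCAAGGGGTTCAGACCTCATGGC
ATTAGGCCGAAATTCCATACACTCTGGGAGCTGGCACCCTTACGACTCAAGCGCGCAGTG
TCCTATATACTTCGATACCTGACCGAGCTGTATTATGGGATAACTGAGCGTAGGACGAAT
TCGAAATTCTGTCGTTACGTTACAAACTCATTAGGACCGTCACCACGCAGGCCAGCCACT
TGGCCGGAACGATTGATCGTCATCCGGATGGACACGCCCTATTGCCTACGCCGCAGGTTC
TCCTTCCCTGGAGATGAGATGTCAGGCCGCCAAGCGGCTAGACATTTAGACATTTCGTAT
GACCACCAGATTGCTGGCAGGGAATTATAA
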