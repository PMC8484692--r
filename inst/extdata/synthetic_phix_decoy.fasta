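>synthetic_phix_decoy length=5400
AAACATTTCGCTTGAAGTGTGGGAGCAGATTGTGTGACCTAGGTATTAGGGCTCAAGTCGGTCAATCTCTGGCGGGTGAC
GCTAAGCGCACGGTGGCTCTTCAGACCCGGGGCCATTAAAAACGAATGATGGCCACTTAACAACGCACACCTACCTAACC
TCACCATTCGAGCCACCCTTCAGTCTTAAGCCCCTGACGACTTTTGGACCGAAGCCGGAGTGTAGTTTGGGAAGGGGTGC
TTACCGAGGATGTTTCGAATAGACCGCGGCCCTTTAACAATAGCATGATTGCCATAACCCTGCAAGTCCCCAAGGGGACT
TTCAAGAACTAGAGGCGGCTCCGAGCATTGCCCCAAGGGTAATCGCTAACGTCTGTGGACGCGTCCAAGGTGAGGCAACC
TTCATTTATTAGTCAGTTTGTTCCGTAGCCGAATACACCATCCGCCGACATCGGATCCCGATTTTTAGGGCGTTAGCACT
TTTAAGATGCACGGACGTCAACGACCCGATATCAGATATTCTGTCCCGTAATAGCACCGCGGAGGTGCGCCGCAAGTTAA
CAAGTCTGTTTTGATCCGGGGCATCCAAAGAGGAATGCTACCGTTTCATGCCGGTAGTACCATTTAATAGAAGGGCAGAG
AAAGACAGTCTGGTTTCAATCCTAGACGTGACCTTCACCGTAGCGAGATGCGCCGAAAGAATCTAAGCATACACCAGTAG
GGACTGCGGCAAACTTACTCGGGACCCGGTACGATATTCGCCTATCAACTTTAGAACTGTTGACTATAGCGTCTCATTTT
TTGGGGCTTCACTGCAGGGGCGCCCAATGAACTGAGTTCCTATGATCTATACATGCGATATCTGGCTCGCTTGCGTCGAA
GCCAGGTCAGGCTCTCCGGCAGGGGAAGTTGGGCGCCGAGTGATTATTGAAATCGGAATGCGCCGCGTGCTCAAATGCAA
CCCTCCGAATGCATTTGGGAAAGGGAGATTTTACTTCATACACGGTCTGCGAATGGTCTGGTAATTGGTCAATACGTGAC
CTACGAGGTGCGCGGAGATTACGCTAGGGCCTAGACCCTTGCCATAATAAATTTACTGTCGTTGTACTCAATCTAATAAC
CCATTAAATGATTAGGGTGGTTAGGCCTTGCTCCGTATTGGCACTTGTAATACACTCTGTGGGGGCCATCACCCCCATTC
ATCTTACTTAAGGGATCGGTTCGATTCTAAGAACGGACTAACCTCATGAAACGTCGACCGTGACGCTTATCTCCTGGACC
CTGGTCACATCTACCACTGCATTTTCGCATTCCGTAACCAGACGAAGTACTGAACTCGATACTGTGTTGTGGGTAATCTG
ACTAAAGCGTGCTGAACAGTGGACTCCACTCTGTAGGTTTCCTCACAGCGAGCAGAGATGCTCCACATTCGGTAAGCATA
CGGAACACCCTCCTGCGAAAGAAATCTTGCCCCGGGAGGAGCCAAGCGGTCACCATATATACAACTCCTTCGACAACCGT
AAGAGATTTCCCACAGATTGCCTAGTGCATGAGACTGATCTTCTTCGAGAGTCATTTCTATCGCTTATTATTTAGGCAGT
ATTACCAGTTAGGCTGTAATGACAGATTACCGACATTAGGGCCAGACTGCTTTGCGCTCTGAATCTACTGAGCTCGGAAG
GGCCCCTTAGCCTGTCAGAGACATAAACCAGAGACAGACGAGCGGGATACATTCAGCAAGGATACTTCAACTTTACCAAC
TCTTTATCTAGTAAGTGTGGGGCTGCACGTCTAACGGGCATCCGCGTAGCATCTTTGCGCATGGTCCAGTCTGTTACTAT
TGGTTTCGACGAAGTAAGGGACGATATGGAGAAGACAGTTGTTGGTTCGTGAGAACAGTGTGACTTTATTGGTTATCCAG
ATAAATCATGCCATAGGAAGTGGTTGCGATAATGACCTATTTAAAACTATTGTTGAGAGGCTCTAAGTTGCTAATAGAGG
ACCGTTTTGAGGTTGTTCAGGAAACAACTGACCAATTAAGCAGAGATACTCAGGAGAGGAAAGGAAGGCGTAACAATACG
TGGGGCTCCTTTTAACTGCAGAATCAGTATCGAATGCCAATTGCCTTATTGCATCCGCCAGACGCTGCTCAGCTTCCACG
AGCCACACTTTTTAAGCGTAAGTGCCGAAATTGAAAAGGTTTGCCTAATATCTCAAAGAAAGCAACATTGGGTGTTTGTA
GGGATTCGAAGAGAGATTCCCTATACACAAAAGCCCATTTCGGTTGCTGGCGTTGAACCGATATGTTAAAAGACCTGCAC
GCTGGAGAGCATTACTCCGTGTACATAGTAGTGCGTTTGTCGTCCAGACGGGACGGTGTTATCACCGAGATATCTTTCAC
TAACCGCCGGAGCAGTTGGCCGAGGGGGCCTGAGATCACCCCTGGGCTGGGGACTACAAATCAGGCGAACTACTTGAAGA
GGCTCCCACTCGATCGATGTATAAGTATGCAACTCCGCAACATACAGGCCCCAGTGAGTAACCGGCGCGGCGAAGGGGGG
AAGGACCTTCACTGCCCTAAAAGCTACAGAACTTGTACGGCGGGACAAGCTGCCTTGGTCAGAGTCAACCTTCGCCCCGC
TAGCCAAGAGAACATAAAACGCATCGCTTCCGGAAGTCCACTCATTACCGCAGTCAAGGATGCCTTTCCGTTTTCCGCCG
TATAGCAGAGCTTCACGCGGCACAAGAGCCTATAGCGGATGAGGGCGATAAAGACTCATCTATTGACTAATTTCCTGCCC
TGCGCAATGAGACCGAAGAATACACGCTGGATGAAAAGCTTTGAGTAACTTAGTCAGGACTAGCTATAGGTTCTCATCGT
CTCTTCCGGAAACAGATCGTGCAACCGATTCACGCTAATATAACACGTCCTAGAGAGGGTTATTGGCGCTAGCTCTAGCG
CGATGAGTTCTTGCCAGTTTGCGTCATCCCAAAAAGAAGACATCGGGATGCCGACTTCGTTAGTCAATGTGGCATACATA
ACGTGCGTGCACCGACTGGGGAGTACAGTTACATGTCTCTTATAACCGATAGTGCATACCTATAAACTATCACATAAGAC
ACTGTGATGCGACTAGATACTTGTAGCCCGTGTACAGGTGGACCTCGATGCGAAACAGTTTAAAGTTATGAAGCCATCTC
GCCCCGCGTGCACACGGTATTATGCGTAATAACATGGTGTCGCCTGTTAACGCTCGTCTCACTTAGACCTGAGCGTTCTA
TCTCGGCGAACTAACTCCAGAATACCAACGTCGGGCGTGTCGAGTGGCGCCGGCAAGATGTATTTATTTTTCCTCGTCCC
CCCTGTAAACTGGCTTAGATTCTTGCGGACAGACGCTGCGGGGGTCACCGGCAACTCTCTGTACCACGTTCTGCACACAC
ACCGTGGTCTCACCGGTGTTGATCATGCCTTAATGAGTTCCGATGGTTCGGCAAGCCTCGTCGTGCAAAACCACAATTGG
TCACAAGTGTGCCAAAGGTTATACCATTAGCGGTGGCAGACTATCGTATCCCTGAGCTGCTTCTAACAACTTCCCTATAA
CCGACCTATCGACTGCGAACATGTAAATCAGCACCTCGTCGAATGATAATCCCGGATGACTCTTGCCTCTATAATGTCCC
CTGATGGAGTATTTATTAACCTCTGTACTGTTCCACTCTAAACACAACAATGTAATACCCCGAGCGGATGGAACCATCTC
CGGAAGTGAATCTATACGGAGCTTCCGCCTAGTGTTATCATGGATGATGAGATTGGTCAGCAACGTGCCCGATCACGCTG
AGAGATTCGCAAGCGACTGACAGACGAGATTGATCGTGGAGCAGTGGCGCGTACCCGCCCCCTAAGCTTAAATCGAATGG
GGAAGTGTTCCCTTTGCGGTCGCGTCGACTAGTCGCAGGATCTCAAACGCGGGGCTCAGCTAAGAGACCGGATTCCGTGT
GTGTAAGTCTCCGGTCCGAGTTGACATAGTATGAGAAAATTTCTCTTTCTCGTGTACTTGAGCTCATAACTAGCGGTACC
CCAGGAGCGTGTATTCATGGACGACATACTGGGCATGACATAATAAACGCTGTGACTGCCTTCACCGGTATAGTGGTTCG
GAGACCTGCCGAGCTACGACTCTGCCCAAAATCGCGACTAGACCGCTTAAGCCGATTTACAATGGTACCGTTGCATCGAG
CGATTTATAGTTATAGAACAACGCGGCTCGTAGACGTGAATATGTAGCGCCCTTTTAATATGGTCTTTCTTAGCACTGTG
TTTCGGACTTGGTAGGTACGGTACTGTAGGAAGAACGGCCTTCATCTCGGATACTCTGTAGACTTTCCCACCGATGCGAA
TGCAGCTTCGTTGTGTCTTCAACAATCGGTAGAGGAAATGTGATCCGCCAGTGTGACTGTCTTTGAGTACAACAGTAGGC
TAAAATCTCGCACCCCGAAGCTTGTACATTATTTCCTTATGGAAAGTAGAATTACTCAACTCGAGCCAGAACACGCCTGC
AAGGCATACTCATCCAGCTCGTCAGGTCGGCCTCAACACAGTCGAATGACACTTTTGACAGGCCGCCTAATCGTATAACT
AAGTACTAATTTTGGTCTCAGGAACAAGTCATCCGGCAGACCTTGTGTCAGCTGCAGCTTTCCGGAATAATCTCCGCATC
GTGCAACTAAGGCCTGAAACGTGAAAGTTAACCCACGTAATCTTGACGGCTGCGACGCTAGTTGAGAGTCTTCAGTGACG
ATGACAAAAGCGTTACTCATATAAGCGTATAGAGGTTTTTATGGCAAGGACGTGAGGAATAGAGCTTGAAAGGGCGGGGG
GATCGTATTTACCTAATACCCTAGATTTCCGATTAATCCTCACAAAGGTGAAAACCGAAAGCTTTGTAAATATCTCCCCC
TTCGCTTGTCGTTGATCGCAGAGTGAATACTGTCGAAAGCACACACGGGGAAACAAGTTTACGTGCTTTCTTGGCGGCAA
ACCGATGTTTATGTCGGCGGCGCATTGTCCCTACGATGTACACATAACTAGATGATTACGTTGTATTGATCGACAAGCAA
GGATTATAAGGGTCGGGGCGCTAACCTTGCTAAGTGCTGTGCTAGCAGCTGAACCAATTGCACCACTTTAGCAAGTCGTG
GTGGGGTTTATATCCGAGAATTACCTAACTGAGATAAGGAGTTCTGCTGTTTCCGCCTCGTAGTCGGTGTCGATGATCGT
CGGGATGTGCCATGTGAATCAGCGTTACCGGTCATCCTATCTGCAGTAAACCTGTCAACTTTCAATAAATACTCTAGACG
TCTCTGTATACCAACTTTCGGACGCAAGTTTGGAACAGCT
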