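>MD06G1208200
ATGTTTGATAGGTTAATGCACACACGCGGGTCGGTCGCTACTGAGACAGGTTATCGCCCG
CTATCGAACAGATCATGCCCGTCAGAATCCTACGCTGCCGGCTCTCTAAAAGAACCTCGA
TCGGTGAAACATCCTAAAGAGATACAGGTTCCGCAAGCCCTTGTCGTGGGCACCAGGAGC
TGCGATCGTGTAATCGTTGCCATCCGTGATTTCTTGCCGCTGAGACATACCTTGCAAGCT
TACTTGCTTACACGACGATGTATCCACGCCGAGGCATACTCGTGGCGTGAGTCTAGACGA
CCGTTTCCGCCGAGGTCGCAACATACGCGCGAGTAA
>MD14G1218600
ATGCAGAGACTCGGTCACAGACACCTATTTGTGGGCGGACGAGGGCTATCTGTTGTGTCT
GGTTGGGCCAGCTCCTCAAAACTAAATGAAACGCCGGGATTACCCACATTCGTGCCACCC
ACCGGGCTTCTAGGACCCTTTGTGAGAACATTATTAGTAAGAAGGCTCAAAGAGGACGCG
AAGGGGCCTACTCCCCAACCGGTGCAAGATCTGCGCACTTTTCAGCTTACTGTATCGGCC
GTAGAGAATCTAAATTCTTGTATGATGTCTCGTAGGCCCCATTCGATAATGGGCATGTAC
GGTAGGAGAGGGTTAGGCCGGGCTCTGGACGTTTAA
>MD09G1236500
ATGCCGTCTAAATCGCATCAAGCGTCCCAGCTCCGCCAGTTGTTACAGACAGATCGTGCA
ATCTCCGGTACGACCTCTCTACGTTTAAGAAGCGCTGCAATGATCAAGTACGCTCCGAGG
AGAGATCACCCAGGTAGGCCGATGGGTACCTATGCCGTGCCTACCACACCGGGAGGATGC
GTTACTCATGTGGCGGTAATCTATCAGAGACGCAGCGTGGCTGGACTCTCGGATTGCCCG
ATGCGCATACAGATTGCGGGTAACAAGGCCTTCGTTGTACGACAATACGAGATGCAACTG
ATACCTCTGGAGTCCGCACGCTTTAGTGGCGAGTAA
>MD15G1373300
ATGCCCGTGTTGGTGATGGCCTTCTCGCTCATGGAACAAGCTACCTACAGCCAACGGACG
GGGTCGCTGTGGTACTACAATGTGTCAGACGTACCCCAGGAAGGAAGGCTCCCGGACGTA
CTCATCAGTTGCTGTGCGTCTACACCACTAGACCTAGGCTTGCTTGGTACGGATGCGCAG
AAGTATCAAACACACGTTACCGAGCCAAGTCCTGGCTATCTTCTCGCGCCTTGTGAAGTG
GAGCGCGTCCTCAAGCCCCCACAGTTGTCTACTTGCATGTGGATACCCTACGCTTATAAG
TATCGGAGCCCTGGCATACCGCTTCATGACCCATAA
>MD17G1266100
ATGGCGAGAAACGATCGACCCAACTCCCTGCTGACGTCGAGACCCCGGCTCATCATGTCC
GACTATCTGGCTCCCCTATTTAAGGACTCTTGGCGGCGAAAAGGTAGTTACGACACACTT
TCGTGCGGCGGCGCTGTTAATTGTGGTGCTCAAAGGGGGTGGGGAACTTTTCACACTTTG
TCAATCAACTGGCGCCTCCTCAGCCAGCGACTAGACCAGCCTGTAGCAAACGTTCGGAAT
GTTACAGGCGATGAATCCATTATAAAAGAGTGGTTAAAACTAGCATCCTTGGCTTCCACG
GTGGTGCTGGGTCCATCACATGGAAGTTTGACGTAA
>MD14G1006600
ATGCGGCCTTGGCCGGAGGTCTATCCGGACACTTTCGTTCATGATAAGTGTCGTTATAAC
GGCCTAACAGCGCATGGCTCGACTTTAGAGCTGTCCCCACTACCTGGTGTGCTTTTCTAC
ATCATAAAATCGCATGCCTCGTACTTGACGCAGAGTTTCCTGGGAATATCTCCTCACATG
ATACCTACTCCTGATAGTCTCTCGGCGAGCGAGAGAACCTACATCGAGTTCCGAACATTC
GAACCTAGCTTAGGGGCTGAGATAAATAAATTATCAATCCTTCGGTGGCCGCGTATGATT
AGATGTGATGAAAGGCCTTTCACAATTGGACTGTAA
>MD12G1009100
ATGCGGACAGGTCACTTCCTCCGTCCACGTGATGCTGATAGTGGGCGCACAGGAATACCT
CATGGTGTAATTCGGCAGTTTGTTGTGTTATCGCGAACTATATCATTACACAACTACATG
GGGCGTAAAACGCCATTCGTAACAGCGTTAGGATGCGAATTCACTACTAGGGAGAAGCCG
CTGCTCACCCGTAATTGTCTCATCTGGCTCGTATCCGCCTTTCAAGCGCCCCTGCGCCAT
GCCGGATATGGGGTCGCGCCCTTTTATGACTGCTTTAGCAGGCATCTTTTGTTACTAGGT
AGTTATTTCGTGGCAGAACGTAACCTGCATAGGTAA
>MD09G1048100
ATGAATGACAAACGGTCGCTCCAACCCCGCTTGGATCTGGCATCGTCGCTGCGCCCGAAT
CGATCGTTGCGTACGCACGTGAAAACACTACCAGTTAACATACCCTCTAGCAACCGCAAG
GGTAAAAAACGCTTGACTGGGGCTTGGTCCCCGATCGCATTTACCCTAAGTGGTCGAGTC
CCCGCCGCACAGGAAAGCGTAATGTTGTGTCCGATTGCTAATTGGAGTATTCATAGGTCG
ATCTGGCAAACTATTAACATAACTTTGAACGTATTTGTGGGAGCTGTCAGGCCCGACCGC
GTCGTACGCCGCAGAGTAAGTGACGCCCGAGGTTAA
>MD12G1009200
ATGCGCGAACTAGGTTTGGGACACAGTATTGCTCTACCATGTAGTCCCATATTATCAAGT
AATCTACCGGCATCATTAGGTGGTGGCGTTGAAACACTACCTCTCTTCCGTGGCGCGAGG
TACGCGCGAGTAATGGGTGCGGGTGATATTTACCCTACTCGAGCACGCTTTTTCAATTGC
GCTTTGTGTTCAACAGGATGGGTTGTAACGCAAGCTGACGTTATCGGTCTAAACTATGCA
TGGACTACTTTGAGCACCAACCACCCATGGGCAACGCATTTACGGCTGATATCACCAAAC
ACGCCCTCGTGGTCATATCCAACGTGTGTGCGTTAA
>MD17G1048300
ATGCGTCCCTGCGTATATTGGCGATTCCAATGCCTTGCGGTCACTGCAAAACCACATCTT
ATTGTTACCATGCGAGTTCGCGACGGTAATAATCCCCGGCATGATGCAGAACGTTCACAC
TCTTGTCATAATGTCACGAAGGTAGTGTTCTACTGCGGTGATGAAACACGCCGGGCAATG
CGCGACTTTGCAATGATCGCCAGAAAGTTGATTTGCCCTGCCAGTAGACTTATAGGCCGA
CAAACGGGCCCATTGAGTTTTTGCGGGGAAACAAAACACCCATGTCTGACTGCTACGCGG
GTAAGCCAATTCCGAGAGGGCTGCCGTTGTAGTTAA
>MD09G1174400
ATGTGCGGAGGAGCGATTTCTGCGCGCGTCATCTTCCATAGGCGTGTCCTATCTGCTGAC
ACTTTTGCCAACATACAAGCAATCAGCAAACAGAACAGCGCCCGCTCGCACTTGCTGACC
TCGATGTATGGAACCACAAGCACAAATAATCTAGGCCAAGGAGGCATGTTAAATAATCAC
CTTGGGCTCCTAAAGACTTATAAGATGCTAAGGTTGGCCCAGGCCGGTGAAGCTCGGCCC
CAATCCGCTTCATACGTCGTAAATAAGGCGGCCGTGGTAGTCGATTACATAGACTCATCT
GCAACCGCTGCGTGGAATCTCCATTGGCAGGGGACCACTGGTGTCTTGTAA
>MD17G1152400
ATGTGCGGGGGTGCAGTACACTCGGAAGAACGCACTCCAGGGATACTACCTCTTCTTAAA
TCGAAGGTACGCATACAGCAGCCACGTCTTAGGTGTGCCGACCACAGATTCACCGTCGGT
GGAGATACCCGTAGATCAGCCACTAAAGAACACGTTTTGCCGGATGCTCGCAGGATACAG
TTTGCACAAACGATCCGGCCCAGTGGTGTGCAAGGGTTACACGCCTCTATCCCATGGCTT
GCCCGCACAATTACGATTCTGTTCGTTCAGAAATATAAGTCAAATATGACTAGTACTTCC
GACACCGAGCGAACCATAACAATTGTCCACTTACTCTTGCGTAGGCGATAA
>MD13G1163300
ATGTGTGGTGGAGCAGTGACTGTGAATCACGAACTCATAAAACGCCCTTACTATGCCGCG
GGTTGCGTGCTCCAGTACTACACTGGTGGTTGCTACTTCAAACCGTCGCAGCCACGTACA
GGTAACGTATATGTCCGGGACGAGCTGTTCCCATGTCTGGACGGATATATATCCTTGGCG
TCAGAGAAGAGCTATCTGTGGGTCTGTACCAGGGTGTCGACACGCTACCGTTTCGTTTTG
TACATAATTACCTACCGAACTAACCGAATAGTGAACTCGGAGGATCATCGATTAACGTGC
AATCACTCTCGGGAGCATTGTAATCGGAAACTCGCGCCAGGCCCTATGTAA
>MD16G1162900
ATGTGCGGAGGTGCTATTCGGCCTAAAGTGCAGCCTACCTGGGCCTGTACTAACGCTGCA
CTGTTCACGCCACTCCACGCACCACGATGCTTGAATCTGGGGGTTTCTTCTCTGTACGTC
CTTCGTAGTGAATGGGTATCTCAATGCCGATATGTCGGGGTACGCAACTGGACATGTCCG
TGTTGTTGCTTCTATATGTTTCTTTCTTATACGAATTCAGGCCTGCGAAGGCAGGGGGCC
CTGCTATTTCAAACCATGACCGGTGTTATCTTCTATGCCTCACTTGGTCAACGGATAGGC
GACGAGTTGCATTCTTGCACCGGTCGCTACCAGTTCGTCCGGGATCACTAA
>MD11G1306500
ATGTGTGGAGGCGCCATTTCTCAACTTAATTCACACATCCGATTATTCACCAACCCTAGT
TTGTACTCCCTTCCGTTGATCACATCTTGCGTACTATTTTTAGATTCCATTCATGCTCCA
CTCCTTCACCGCTTAGCTGAGTGCGGCAAACTCGCGTGCAGCCAACGAACGGAGACGTTG
ATTAATCCAATTGATGTAGCAGCAGCCGTGGTTTCGGAATTCGCCGAAATTCGATGCAAG
ACCACTAGTCCCTGTCTCCCGTGGCGAGTTGTCAGTAGGTCTTTGACAGTCATGGGCGAA
CGAATTACACCACTGGAGAAGGTAGTGACCTGGCACCACATGGCCATATAA
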