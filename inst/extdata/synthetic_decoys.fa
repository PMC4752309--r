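>synthetic_tRNA_1
CGCCACGCTCAGTGAAACTGAGTGCCGAGAAGAGAGAGCAAATTATTGCCGGCTATTTGGGGGTATCTGG
TAAACTGCCAGGGCACTTTGACGGGGTGACACTGCTTTTACATGTC
>synthetic_rRNA_2
TGACTCAAATATAAAATTCTGTCACACACCGAGAAATATTTTGACGGAGTGTCGTAAGGATTTCAGGTAT
CGGAGGTATGGACCTGCGATAGATTGGTTTTCTGCAAACGAGACTTCCATAGGTAGACTTTGCTAGGCAG
AGTTATCTTGAATGAGCACGTCTCTGGGCGTTTCCTGTAGCCGGATCACAAAAGGATATCTAATAGGATT
AGTGCGCGTCAGCGTTTGACAGTGGCAAATAAGGTCGCACTGCCCGCTAAGGCGGATGCTGCGCTGATAA
GCTCA
>synthetic_snoRNA_3
GCAGATCCGAATACAGAGACAACGGTCCGGCGCCGACTTGCACGCCGGCCTAAGGTCGGAACCGTTCGGG
CGGTCCGAAGAAGGCGGCCAGCGCCCTGGGCGAGAACGGTACACGAGAAAATGGATTCTATAGTGGACCT
TAGAAACACACAGAACCGTTGGATATTGGAAGGAGCAGTCTTTGGCACAGGTCGATTGTGACGAAGGCGA
CATAGACCCTCAGTTCTGACACC
>synthetic_snRNA_4
GAATTCAGGATTGACGGCTAGGAATTGCCACAATTAACCCCACTCACTAAACTCTCTCTCGGCCATGAGC
GTCGCTAGTACCGTTAAGGCTATGATACCTAGTTGCACCATATAAACTCAAGTATCGGTTCTAACCGCCT
TGCCGATTTTTGCTCTAGGGAAGCAGATACTGAAGGCGGGCGTGTATGTCCTTCGCCGCTTGGCAACTAT
TCCTGTATTAGGGATGAGCATCCGAACTGGATTTGATACACCCCGCGACTATCTGAAACCCTCATCGAGT
GGTTATGCCCGAGG
>synthetic_tRNA_5
ACGAGTGTGGCGATTCTTACGTGCGCAGGTTCGCACAACATTCGAAATGAGGACCACCAAAAGAGAGACA
ACCGCGCGGGCTCGGCATACTGCCCCGCATTCCGATAGGGCACTTACCACTCGAGCTATAACTGGCGACC
CCGGGGGGAAAGAAGACACGGTCAGAAGCATAGTCTG
>synthetic_rRNA_6
CTGATATGGGAAACAATTTCGCTGCGGACTCACAAGTGACCGTTTTCTTGGTCGGTAAGTGATGTTCCGA
GAGTGGATTAGTAGCCTCATGGATCTATTTTGATCTGTAACGTTTTCAACGAAGGAGTATCTTGTCATGC
AATCAGCTGACGTGTACTGCACCACACACCACTGACTGGCCTTCGCCACATGCACCTGCCCGCGAAATCT
TAAAAGTGACATGGCCTGCCCGAGTGGCACACCGCGGCCCATTGACCAATACAAGGCG
>synthetic_snoRNA_7
TGAATCCATGCTAAGTGCCACGTACATGTCCACACACCTGGTCACCCGCCGGTTGTGTACCGCTGCATCA
GCGGTGTTCTAGAGAGGAG
>synthetic_snRNA_8
AAATACGTTTGGTTAAAGTCTGCCTCGGCAATCTTACGAAGCGCCTTGGAAAAGGCGCGGCGGGTTAACT
CGATCCGACTTGGAGATTCTCAAATGACTCGGGGGATGTATAATGGCTTGGGTTAACATTTAGCCCGTCC
ACCAGTGCGCAAAGACAGTCATAGGAGCGGGGCAATACCGGTGACGAATATATTGGGTCGTGGATGGATC
ATGTCGCCTTCCGCCCTCAGGTTTCATCCTACGGTCCCCTGCCATTACAGGAAGAATACTATCGCGAGCT
ATAGCGGGTACA
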