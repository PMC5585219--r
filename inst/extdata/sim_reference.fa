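>locus01
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATATCCTTAGTAGTCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAGACTCGTGCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAATAGCCGGGCCATGTAACACTGATGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAGTTCCTGTTAGTTTTGGTTAGGCACGGAACGCTATCGAGCGCGTAAGCGCCAACCCGCATTTACGAAGTACCCATCGTATGTAATAAGACCTCGAGTACGTCGGGACGTTGGCTGTGATGTTTTGATGAGCGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGACATCATCGCACGACTCGTCATTTGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGATGTGGAGCGAGGGTACTGATAGATATACGACAATGCACGTAGTCTCGATACGTCATTGGTACGAACAGTTCGTATTCCCCATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGAATGCAGCCCAACAGCTTGGCCGGATCAAGCAGGATGAGAGG
>locus02
CACTTACTTTCCCCGCTACGATGCTTTGCACAAATTCTACCGCATTGATCGTGGATTACTAGTTTTGATGGCATGGGTAATGGTGGAGCCAAACATCCAGCTAGCAGCTGCAAGCTTTGCCTACGTGGAGTCTCTGTGAAATTCAGAGATACGCAGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAGCCTCGTGCAGCCCTCACAAATTTCCGCCATCAGTGATTCAGTATTGTTTCACCGCAGTTACCGTGAAGTGCCGCCATATACACAGGTTCATGCTAGAGAAACTGCCACCCGGGCTTGCCAACCGGCAACGTGGCGTTGATTGACAGAGCTTCTTAAGCCGCTGATGTCCAAAAACTGAGTTAGTTCGAGATAGTTGGATGTCGCACTAGAGGGAACAGCCATAGGACCGATACAGACAGTTCAATGGCGGATGCCCGCACCTGTATACACCTAGTATGTAAAAATTGAATACGAGAGGGGCACCCTTTTGCCCTCCCACTGTCTATTCCAGGTCGCCGAATATGTCCCGACTTCGACCCGTTTGGTAGGCCAGGGGCCTGGGCTAAACACGGCCTTCCCGATTGCCATGAACTCGTTTCGCCTTAAAGTCCAACCGTAAAGAAGCGACAGCGACCTAATCCGAGCTTTATCTTTTAAGCGGGCGCGGGGATGGAGTCTAAGGCACAGACGGATGCTCATCATATCTCGTAGCATTCATAATGTTGTGAAAAACGGATAGGCTGGGTCAACAGATATGTGTGGTAGAATTACCGGCAGCTCTTTTGCCGGTGGGTGCCCGGCGACCCGAAACTCGGATATGCATGGGGGAGGGCCACCCATTTATGTGCGAGCTGGAAGACGGTTCAGCGGTCCCTCTTTGGATCGATTCCAAATGACTAACTACGAGACGTGAGGCGTATAGAAACTTAGCGCCGTAGCAGAGGAATCAGGAGAGGCTGGTAAAACTAAGTGTGAAGTATAAAATGCGGC
>locus03
GCAGTTTGGTAGACTCATAGTATAGGACGCATACTCTGAAGTTCGAAGCGGTTCCTTTTTGCTAATTAACCAACAAGCCACGAGAGTTGTCCTCGTGTTTCGCAGGGTAAATGGACATTTGCGGCCGCCGCTCATGCTCGATATGAATAAGTTCAGTGGGATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACAATCCCTGTGGCACGGCATGGTGGGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCTACCGTTCGGCAAACATATTGCTGCAAGATACTATTAGGTGGCTGGACTTGGGCTAGTGGCCGACTGCTAAGTATTCCCGTTTCAGTATACTGACACGTGAATCCACCAGGGAAAACCTTAGTAGCGGCCCGGTATAGCCAGCATAGGGTAGTAAGGGAGGCCATCAACGATCGTGCGGTGTGGAATCCCAGAGAGGGTAGGAGGCTAAAGCTGTTGAGGGTAGGACTGACAGTGTGAGCGCGAAGGTCGTGTCTTCGTTAGGCTGACGCACTATACCACGTCATACGCTATCATGAATCTTCCTTGCTGTTGGGCTAAGCGGGGATCGCTTACGAGGTTAAATCCCGCTCTTACAGGGAAGAGAGAGTCTTCCTTACTCGAGACCCATAGTACTATGATTTCGGGCAAAGAAGACGGGACCACTAATATTTGACGGCTCCAATCTCATGATCGTCCGGGGCATGCAGCCCTACATCGTCCCAGCCCGGCTAGTAACGGTAGATTATCGATGTAGCGTCAAGGCCACCCATCGCTTGACGTAACAGGCCTCGTTCAAAGCCGAATCAACTTGGAAGTCTCACAGGTTCATGCTGCAGGCTGGGTGCCGCTTACACACGCTAAGACAAAGACTTGCGCCAAAACGCTGGTGCTAAAAGAGCT
>locus04
TGTGATGCGTACGAGGCCGCGCAAATTTCAGTTAGACACGATGACCACGAAATACCGGGGAGGTTTAGCTTGTTTGCTTAATCCCGCCAAGTAAATAGCCCAGTCGGACGCGGCTTCCGCTAGATAACCGAACTATTCAACCTATCCAAATGTGGCCTAAAAGCTTGATTCTCAAGTTTCCTATTAGTCAGTCATTTGGTGAACCACCGTGGAGGCGCATATTAAGAGTATACTATCGAGGAATTGCTGGATGGATACTATATTTCCAAAACAGCACTGTATTTGACGCCGCTATGGCCCTCGTGGGTGACATGCTGGGTTAGCTAGCCGGGCAACAACTCTTAGCGTTGAGTCGGGCTCAGAGTTGCACCCGTTGGCTGGGTTAAATATATCACACGGCAAGCGATGCGTCATGTAATAGGTGCGGAACTCCAGATTGGCGATGTGCAATTACTGTGCGACTTGTCATATCTACAGGGGACTCCAGAATATCACGTACTTCCCAATACCCAATATCTTGCAACCAAGCGTTTAATCACCTGTTAAATTGTGTAGAGTAGTAAGCAGATTACTGCGGAGAGAGAGCGCGAATCTATACTACGCTCCGTCTGGTTACCGTTGCCTGGTAAGAATGACTACGGCCTAGAATGGGTCCACACCCTGCCTCCTAAAATTGCACTGAGCAGCAGAGCAACGAGTGACAAAGCTGGGAGCCCCCAATAGAAAGTACTGGATTTCTATGCCACATGGGACCGGCCAATACATCATTCTGGAATGTTCCAATGTTGCTTCGGGATCATCTATCTTGGGCGGATAACATACGGGTACGTGCCTTGGCCGTCCTGCTCACGTGCTCGACGCTTACCGACATAGCTAAGACGTGCGCTGAGGTTACTACGTCTGAAATTCCCCAGCGTTAACAATTAAGACCGTTATGCCACTAGTGTAGCTTACTGATAATGACAGGTACTAAAAAGTGCAATACCATCACGATCTATCA
>locus05
TAGGTGTCATTGTAAAATCACGTCTATAAGACCTTTTCTGCTCTTGTACGGGTGCGATTAATACGTCTTCGGCTTAAAACCGCATCACAGCGTTGTTCTCCAAGATACAGAAGGTACCCTTCACTATTAATATAGAGTCTGATTCCCAAGGTAATTAAACACTTCTGAGACTTGTAGACAATGCAGTGCCTCACCTAGCATCGGTTGTCCGCAACAAGAGGCTTCTTGCATATGAAGAGTCTTCTCAGCACTTGTGTTTACTGTTAGGCTGTCCGTATAAAGCTGCGCTAGGTCGAGCTCTCGTCCTTCCAGGCAGTACCAGTGTCGTGCGTGCCCCCGTGGTCGGATTAACTCACCCTTATCAAACTGGCCCATCTCAGGTTCGCGCTTACCGACAACCGCCACAGTCTTACCAGCATCAGGATGACGGCCTGTGTGGACTCGTGTCACATCGACATTTCTGACAGGAGTACTGGTTCGTATTCCCGTATATCACACGCGAGCGAAACGGGCTGCGGTGTATATTAGAGCACTTATGAAAAGACCGGAGTCTATATTGTCATGGACCGTGGAAATATGCTCCCTGCCGGTGGTGCGTCGGCGAAGCCAGTTTGCGAGACATGCATCTGGTACTAGTGAACTGTGAGCTTAGTTCTCGAGTCCCAACGAAGGACTTCGAGCCAATCCTCTCACTGGTGTACTGATTTCTTTAAGATACGTTGCCACCTTTCGTTCTGGTCGCTGTCGTAGCTTGGTCTAAACGGGAATTCTATATACTCCTAGACGTGTCATATTCGCTCTTTCATATTGAAGCTCATCCTGGTATTCCCTCCACCTTATGTTCATGTAATTCTAAACCGGAGACCGGATATTGGGCTTAGTCTGCATCCGAACATATCTTGCTACGCCTGCATAGTCAAGCCCATGCCGTCGGTCACGTATGTAACCGAACGCCTGATCGGAGCCTACTGAATTCGTGTTATCAGACACGACAGGAAGC
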