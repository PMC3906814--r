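>marker_01 synthetic lin-like mobile-element marker
ATGAAGAAGTTAGCGGCACTACTATTCTATATTAAACTGCTATTCTCTACCAGTAGCATGAATGCTTATG
CAGTCCATGACTCCGTTAAGGTCTTTCGCACATGGTCGTGGGTCGATCCAAGCTACGATAATAGACATAG
TTACGGCTTTTTTACAGAAGGAGGAATTCAGTTATACCGTCTCACTCTACCAAGCTACGATGATACCAGC
CCTCCAACGTTTCAAATCCGTCCCCCTTCTGCAAAGGGCGGTAATAAGATCAGTTTCAGACTTAATTATG
AGCCGAATGATGCGGTGATCCCGAGGTCGAGGTATTTGGGGTCTCATATGTCCTTTTCTGGTCCGGGTAC
GCACTACCAGTTGGTATATATAAGCCATGATCCTAGAGACTTAGGGTTAAGTAGTCATCAGAACGTGATT
CTAATGAAAACTGCATTCATCGGACCACCGCGCTTTCTCAGCGCGCAGGTGGCAACGGATGTACGATGGA
ATCAGTTGGTGAAAGTTGCGGCGGTTAATAGGGATTAG
>marker_02 synthetic lin-like mobile-element marker
ATGACAGATCTTCTGTTTGTGTCTGTATTTTACAAGGTTAGGTACAACCTACTTCGTGGCAAACTAGGAA
CGGGCTTGAAAATTATTTCTTGTCAAAAGCAAAGAGTAGACCTTAAAGTTAAGTTTGTCGGCCTAGTCAT
TTTCGTTAATAAAAACAGAAACTTAACTTCGACAAGGCGCACACTAAAAGCGACTAGGATGAAATCAGAC
GCATTTCGGAGATCGTTGGCGTCTACGCAGGATCGAGTAAGTATGGCATGGAATAGCGTCCATAAGCTAC
CCTCGCTCTGCCTAGGAACATGCAGTTCATTAATCCGCACCTTAATTAGGACCCAAGGAATAACTAGTAA
TAGCTTGATGCTTCTGGCAGTCATAATAGAACAGGAGGTACGTAAGGGCTGCTTACTGCAAAGAGTTCAG
ACACAAGTACCAGTTAAAACTTGTCCGTTAAGATTTTGTCGGTTTACCTTATACCGAAAGAGGTTGAATT
TTGGACTTATGATATCACCAATTATATCGCTCTACCATAGTACAGCCTATATATTTACGCAAAACATATA
A
>marker_03 synthetic lin-like mobile-element marker
ATGTTACGGCATAAACCCTCCAAGCCTTTAGGCAGAGAACATGTAACTATTAACAACTCTACTACTATAG
GAAAGTGTAGCAGAGGCAACAACAATTGTAAACAGTATTTTTATTGTGTTTGGACTAGCCACTATACAAC
TAGCACTGCACAAGAGCAACCCATGTGTCGGTACGACCTAGATTTCGCGGCATCGTTAGAATCACATATG
ATTGTCCTGAGCCCTACCTTAGGACTATCCTCCCAAGTCAATCCTGTAAGGAGATACAGGAAATTTGGGA
CTCGGAGGAAAACTTCATTTACAGGGAAGACCCGAAAGGATGGGCACGTTATATATCTAGAGTACTCCAG
GAACAAGATCGACCATTTTATCGCCAGTCCTTGTTCTCACTTGTTCAGTTGGGGGATAATCGGAACCTCC
GTACTACACGTTAGTTTACTACAAGACAACGTGATTAGGGGATTCCAGTTCAGTACTATCAACTGTAGGT
TTGGGTTTAGCACCAACAAGATCCATCTAATAATAATAACTACTAGGAATGTCTCTTCACATCATCTGGA
TTATAAAGTCGTATGGCCGGTGCCCGTATCGTGGTAG
>marker_04 synthetic lin-like mobile-element marker
ATGGAAAAGTCATCGACGAGCATGATCATTTCTCTTGTTCTAAAAATGGTCGTAGGCCTCCTTAAAATCG
AATTAAAGGCATTTAGTAGGTACTCACGCCAGGGTGATTGGAACAGAACTTCGAGTTCGAAAGCGAATAC
TAATCTTCGTAGAACACGTCGTAGCGGACATCATGTGAAAGGATACGCTATCATGAACCTAAGATCGCAT
GTAACCATCACTGTAATCGATGTACTACATAAGCGGACCTTAATTCGGATCCATTTACTCATTCATTTCC
GCTTCTTTTCAATGGCGATGCTTTTACTAGGACTACAGTGTCAACTACAACCAGTAATGCTGCAAATCCA
TTTACGGGTCTTAAAATACAAGGTACAGTCTTCTCGCAAACTACTTGCCAGCAGAACAACTGACATTAAT
CCGCTCAAGTTTAAACAAGTGCTCCAGCATATTTTTGTCAGACTTGCCACCTGGAAGCAACAACTAGGCA
ATCATGATTTCTCTTTTGCCATGCATTTGTTCTACGTAGTTCGTAAATGCTGCCCCTACTAG
>marker_05 synthetic lin-like mobile-element marker
ATGTTAAGGATCACGACATGCTCCAACGGCAGGGTTGTACCACGTACATGTACAAAATGTTCTTATAGTG
GCTTACGCGTGTTGGCTCAACTAGATTCAAGAAACCTGGTTTTGTCGTCGAAAGTATATCCTCCGAATCA
AATCTCGACTTTTCAACATCAACGGAGGGTATTGCTTTTAACTTGTCATATCTGGCTATATTGTGTCAAC
TTATTAAGGTTATTCTTGCTTTATGGCGATAATTTAAATCTGAAACCACTGCATACCAATAACAGGGCAA
AATTTAGCAAACCTACTTTGTGTATAAGTTCTAGTTTAGATAAAATCTTACTAGCTCGTGGGATTGCCAA
GAAAAGCACAATCCATGGAGCAGAGCCACGTGCTGTATACCATAGGCTGGGGCCCAATATAGAGGGAGCA
CAAACAAAGGGGTGGTTAGATGACCCATATAACCGTAATGCACCGCAAGTTCAACACAGTTTACAGAATA
GATAA
>marker_06 synthetic lin-like mobile-element marker
ATGAATTACAGTTGTCGGACGCGACAGGACGTAAATAGCTTTGAGAAAGGAGACTATAGGAAGAACGCTT
ATCTAGCCGCAGTTTTCGACAAACTAAGCGTACCAGGCGAAATTGCTTACAAACTCTTACCTTTGAATGA
TACATCGAGGCTAATGACGGTCTTTAAAGGCCGTTATATCGTTTACGGTTTAAAACCGCTACCAAAGTTG
TTACTAGGCACAATGCCTGTAGGACATTCTCCGCATGGTACTGTTCTTTGGATAATCACAACGCTATGTG
TTGTCGGCAAGTTTATAGATTGGAGCTGGTCTTCACATGTGTCGTGGTTCACTCATAGGCCAATGAACCT
GTGCAGCGGCAACATTATCTTTACCAGTGACTGGACACAACTTTTTTCTCTAAATGAGTTGTTGTCAAAA
CACGTCTCGAGAACAACATTGAAAGCCATATTCATTAGTAAACGCCATAGGTGTCAAGTTAAGCGGCTTA
GAAAAACATATACTAAATAG
>marker_07 synthetic lin-like mobile-element marker
ATGGCATCTATGGATAAGCAACTTAGTGCTTTATTTAAAGACTCCGGCACGGTAGTTGTACTCTCCTCTA
ACCGAGCCGGGACGGAAAAGATTAGCACTATAAGAACCGTGTTTCATCTTATCATTGTACTACCACAGTT
CCAAGCACAACGAGACTCTCTGGCAAATACCCATAATGTGTACAACGGCTATGGAAGATGCCAGAGCGAG
CGATCGCGGTGTCAGCTAACACCGCGAGTAACACTGAAGAGGATTGGACGTCATTGTTCGGTATTGAACA
AATCTATGGTTAGCAATTCTAATTTATTAGATTGTGCAACTAGACCTATCCGGCATATCATGTGGACTGT
GGCAGCAAAATTTTGTCCCAGCGGCGGCCATGTGAACGACACGAGTGATAATAAGATTAGGCGGCCATGT
TTGATCAACAGAGTGTTCAATCTTCAATTTTTTGATCTGCGCCCACTATCACACCATTGTTTTCCATCCT
GGAAATGTAAGTATAGTAACTGTTAA
>marker_08 synthetic lin-like mobile-element marker
ATGTTATATATGGTAGTAGGGACCCTGCTAAGGTCATATACACATCTACGGTGTAGTAGACGTATCCCCT
CAGATTATAGCGCAGGGCTAAACAGAAATTCTCGGTTACCCCAACAGTGTGTCCAGACCACGTTCATTGA
GGAATCAGTAACTCTAGAGTGTCCCGGTTTAATAAGGTTGTGTGTGAGCGAGTATGTGGGTCAACTGGCA
GAGTGGAAGCATTACTTATCTAAACTCCAACAGATCAACGTAGCAGGACTACCTACATATCACGGAGCCG
CATTACTTCTTTTGTCTTCGAGGCCGACTAGCACATGTTTCAGGATAAGCCAATCTGTGTCATATCCTTA
CCTTTCTAAGATAACTAGGCGAGTCCATGACATCCATTTTTCGACGGTGTGGCCACCTGGGAGTACTTCC
TCCGGTTCCTGCTCTAACAGTTTACAGTGTCCGGTCCGTCCAAGGGGAATCGAAGTTCTAAGCACTATTC
AAAGATGCGTCGTTCATGATCTAAATTTGGCATCAGGCTTTCGAACTTCTCTACTAACCCAGACTACTAA
TCGCTCTATACATTGA
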