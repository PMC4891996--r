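>TRBV2
CAGCTTGTGTGCTGCACAAATCTCATGTTACTAAGGTTGGGCTGATGCTAATTCCGC
>TRBV4-1
CGGCATCAATTTCTACTCCTCATGTGCTATGCATCAACCTCTGAGTGTCTCAGGGTT
>TRBV4-3
CACAGGCCTTTCTACGAGAGTTACCCCCGTAGTATTGTTCTCTACTGCATATTTGGA
>TRBV5-1
TTCCTATTTAATATCCCGATGGAGGCGCCACCTAACCTTCACACATGTGGTGTGCAC
>TRBV6-5
AGAACCGGACTGGCGGAGCCGCGCTCTTCGTGGCCCTGAATCACGTGCTGGCGGCCA
>TRBV7-2
TCAGCGGAATCACAGGTGTTGATGTAGGCGGAAATTCGGCACTATTGTTTCTCTATT
>TRBV7-6
GTGGACAAACATACTTCTCAATTATGCCTACATAAGCTGACCAAATGCGATGCATTT
>TRBV9
ATAGAACAGCGGAGAGCCGTTGGCCGTTCTCAGTCGCCCACCCGATGTTTGGGGTCT
>TRBV12-3
CGCCTGCATGACTGCTCTTAACAAGACTATGATAGCTCGTCGAGATGCGTAATATCA
>TRBV19
AATTGGGAATCATTGGGGCTGAATTAGGGCCAGGTCTGAGGCCACTGTTGGAGTCAG
>TRBV20-1
GTGAGAGAGATTTGAGTGAAACACGGAACTCTTGTAAGTAAAAATTGCGCCTCTACT
>TRBV28
GATGCGATGATACGCCCTGCCTGGTAGGTTACATTCTCGACTGGCTGTTAAACTGTA
>TRBD1
GGGACAGGGGGC
>TRBD2
GGGACTAGCGGGAGGG
>TRBJ1-1
CAAGGATACGTCTTCGGTTAGATGCTCAACTGGGCAAGCTGTACTATAGG
>TRBJ1-2
GGAGAGAGACTATTTGGATGCCGGTCCGTCCAAAGGGAGGTGCAAATTAT
>TRBJ1-3
ATGTGAACCTTATTCGGCTCCTGACCCCGACAAACTGTTGTCAGTCGTGT
>TRBJ1-4
TCTCGGGAGGACTTTGGATAGCGAGCTAGCCGTTACAAGGCAGGAGTAAG
>TRBJ1-5
ACGAAATATCGTTTCGGGGAGGCAGCAGTAACGCAGGATAGAGTTCACTG
>TRBJ1-6
TTGGACTGAGCCTTTGGGCTCAAGTGGAGCGACTTAACGGTATTCGAGGG
>TRBJ2-1
AGTCCCAGACGCTTCGGTGGTGTACGCTCATGGCACCGAATGTAGAAGGC
>TRBJ2-2
ATGGCGATTTGGTTTGGCCCCCATGCCGGAGAGAGACATGTTCGAGATAC
>TRBJ2-3
ACTTCCGTAAGTTTCGGCGAATGATAATATTAGGTATATTGACAACCGCA
>TRBJ2-4
CGTTCGTATGTTTTTGGTTCTTTTCGCGGCGGATCCATGGCTCTAGCGAC
>TRBJ2-5
AAGCTCGCGTTTTTCGGTAGGCGAACCTCTGTGGACAGAGTACAATAGAT
>TRBJ2-6
CGTCCATATTTTTTTGGCTTCTGAACCGACGAGGCTTCGTCCAGATTAGA
>TRBJ2-7
CTGGCCGGGTACTTCGGCGGTAATAAGAGGACCCGTTCTATGTAGGGCCC
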