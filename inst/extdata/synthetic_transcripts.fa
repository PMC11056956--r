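>NM_008829.2 synthetic stand-in embedding the Pgr primer pair
AGCTCCTACTGCCATGAGTGCGCTTTGAAGCTACTCGCTGTGCCTTACCATGTCTTACGTTAGTTTCGATCATGTCCCGACAACGGATAAAGGAAGCACCTGGGCTGCCCGGTATCCGGCGAATGCTATTGACGCTGTGAAGCGCGCAGGACTGAGGAGTCAAAGCCAGGAGAGGTGCGTCAAATATTGGAAGCTATCC
>NM_008263.4 synthetic stand-in embedding the Hoxa10 primer pair
GCATTGATCTGGGAGGCGATTTTATACGGCGGCAGTTCCAAAGGCGAAAATCGTTTGATAGGTGGGTTGACTAGACGGCTTCACTCTATGACGCAGCCTTACACGAAGCACCAGACCCAGTGAGGGGTTCGCTAACAAGGGCCACC
>NM_016780.2 synthetic stand-in embedding the Itgb3 primer pair
ACCTCTATCAAGACGCCATGCAGCCTCCTGGGCGTTGTTGTTGGAGAGTCAATTATCACCAGTTTCTCAGGGTGGAAGCACACTTCTCGACCCCAGGACAGGAAAGCCATGGGTTCCAAACTGTATTCGGCATTGTACCAGGCTGTGTGACCCCGATGTAACCTGAAGACCGGCACGGTCACGCGTCTTACTCGTATT
>NM_008501.3 synthetic stand-in embedding the Lif primer pair
AGCTCCTACTGCCATGAGTGCGCTTTGAAGGCTGTATCGGATGGTCGCATTCTTACGTTAGTTTCGATCATGTCCCGACAACGGATAAAGGAAGCACCTGGGCTGCCCGGTATCCGGCGAATGCTATTGACGCTGTGAAGCGCGCGAGAGGTGCGTCAAATATTGAATGTGCTTTGCCGTCTGTGTGAAGCTATCCTATTCTAACGGCTAGACGCC
>NM_001289726.2 synthetic stand-in embedding the Gapdh primer pair
ACTCAGCTCCGCTTGTTATGCGAATGAACAGGTGGACCTCATGGCCTACAGTCCCACTGAAGAACGGTTGCGACTCTCTTTCAGCTCGTAGCAAGGACACTGATCAAGAGAGGAAACTGCTTTAGAGGTCAGGTTGCCTACG
>NM_007475.5 synthetic stand-in embedding the Rplp0 primer pair
ACCTCTATCAAGACGCCATGCAGCCTCCTGGGACCCGAGAAGACCTCCTTAATTATCACCAGTTTCTCAGGGTGGAAGCACACTTCTCGACCCATTGAAATTCTGAGTGATGTGCCCCAGGACAGGAAAGCCATGGGTTCCAAAC
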