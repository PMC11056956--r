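"gene","accession","primers","expected_bp"
"Pgr","NM_008829.2","CTACTCGCTGTGCCTTACCATGCTGGCTTTGACTCCTCAGTCCT",139
"Hoxa10","NM_008263.4","GGCAGTTCCAAAGGCGAAAATGTCTGGTGCTTCGTGTAAGGC",86
"Itgb3","NM_016780.2","GGCGTTGTTGTTGGAGAGTCCTTCAGGTTACATCGGGGTCA",138
"Lif","NM_008501.3","GCTGTATCGGATGGTCGCATACACAGACGGCAAAGCACATT",156
"Gapdh","NM_001289726.2","GGTGGACCTCATGGCCTACACTCTCTTGATCAGTGTCCTTGCT",82
"Rplp0","NM_007475.5","GGACCCGAGAAGACCTCCTTGCACATCACTCAGAATTTCAATGG",85
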