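>seq1
GTCTGTGGTTTtttccgtaaacccaacacaaacaaaccctccgcc
gtgaaacggtggcccccgatcaagtggggtctatgaagttatgtg
agcggagcgtaatatagcgtatacaactagatcaccttgtgcagt
gtgattccgccctctcctggctctctctcgtcgtgggcatatgtt
>seq2
gtctgtggtgtacttgcataaccggatcttcaaccatctcgagga
cggtgtgtgtggtttttccgattagagggttaggtgtcagtggtt
tgctttctaattgatttacgatatatggatcctggacacacacac
tgtaatacttggtggatgccccggatgttaaggatggcgcacatt
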