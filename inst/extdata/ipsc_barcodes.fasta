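>BC01
GTGCCGACCAGTATC
>BC02
ACCACCTGACGCAAA
>BC03
ACGGCCCTATTTAAG
>BC04
AGCCCTGAGTCAGTA
>BC05
CAAATTCAAGGCGAT
>BC06
AATCTTGTATAAGTA
>BC07
CGTCACATTTGAGTC
>BC08
GGACCTTCTTACGAC
>BC09
TACCAATTGTACGCT
>BC10
CGCTAATGTCCGTTT
>BC11
ACCCTACGGTGGTTC
>BC12
TGTCCAAGCTGCAAT
>BC13
GTGTATTTAAAGCCG
>BC14
ACACCCGTATGTCAC
>BC15
TCTTTCGATGGCGGT
>BC16
GAGCACCCGCGTATT
>BC17
TTATTATGTTCTAGC
>BC18
AATCTCTGAAACGAA
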