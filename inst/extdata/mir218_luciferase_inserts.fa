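>Gabrb3
CCTTTATTTCTGTACTAACTTATCTCATAAGCACACCCAATTCCTCCTAG
>GluR2
TATTGTTAGTCTCTTGATTCATAATGACTTAAGCACACTTGACATCAACT
>Dnmt3a
TTGGTTGTCTCTAGCCTGATCAGATAGGAGCACAAACAGGAACAGAATAG
>Ube3a
TCTTTGTAGCTGGACAGCACAATGTTTATGATTTATTTAATCTGTAGTTT
>Nrxn1
AAACTTATTTACTTTCCTTTTTATGAAGCACATACAAAAGAAGACAGGGA
>Sema6b
CGGGTGGGGATCTCCTCGCCACAGGGAAGCACAAGAGCCCCCTCCATCCC
>Gng3
CGCACTTATCCTGAGATTATCTGAAGCACAAGGCCCTCCTTACCCACCTC
>Mecp2
TTGGGATGTTTTTCTTACCGACAAGCACAGTCAGGTTGAAGACCTAACCA
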