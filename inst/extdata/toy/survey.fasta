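>T001
ATGCGATACTTGGTGTGAATCAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACCAGTATTGTAGTCTGGAGAAGCGTC
>T002
ATGCGATACTTGGTGTGAATCAGTGAATACTGAGTACTACCTCCTACGGACATTGTTTGCTTTGATCTTGCAATTGACCAACCAGAACTAGATGACCAGTATTGTAGTCTGGAGAAGCGTC
>T003
ATGCGATACTTGGTGTGAATCAATAAATACCGCGTACTCCTTCCTAAGAACATTTTGTGCTTGGCTCTTGTAGTTGACAAGCCAGAACAAGATGACAAGTATTGTAGTCTGGAGAAGCGTC
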