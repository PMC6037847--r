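>TOY-ALPHA-1|Genus alpha|ITS2|DrugA
CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACCAGT
>TOY-ALPHA-2|Genus alpha|ITS2|DrugA
CAATGACTACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACCAGT
>TOY-SPUR-1|Genus spurium|ITS2|
CAGTGAATACTGAGTACTACCTCCTACGGACATTGTTTGCTTTGATCTTGCAATTGACCAACCAGAACTAGATGACCAGT
>TOY-BETA-1|Genus beta|ITS2|DrugB
CAATAAATACCGCGTACTCCTTCCTAAGAACATTTTGTGCTTGGCTCTTGTAGTTGACAAGCCAGAACAAGATGACAAGT
>TOY-GAMMA-1|Genus gamma|ITS2|DrugB
CAATAAATACCGCGTACTCCTTCCTAAGAACATTTTGTGCTTGGCTCTTGTAGTTGACAAGCCAGAACAAGATGACAAGT
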