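>P1_F L1HS
GACATCTACACCGAAAACCC
>P1_R L1HS
TCGTCAAAATCATTCTCCATCC
>P2_F L1PA3
ACCAGCCACTGCAAAATC
>P2_R L1PA3
CCAATTTGCCAGTCTGTGTC
>P3_F L1PA4
ATGCACAAGCCTCAGTAGCC
>P3_R L1PA4
TCCATTCTCCCCGTCACTTTC
>P4_F L1PA5
TCCACACCAAAACCCCATC
>P4_R L1PA5
CTCGTCAAAGTCATTCTCCATC
>P5_F L1PA16
GACAAAGGTGACATTACAAC
>P5_R L1PA16
CTTGGGAGATTGTGTGTTTC
>P6_F L1PA17
AGAATGAAACTGGACCCCTA
>P6_R L1PA17
GTCCAGAAGAGTATTTCCTA
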