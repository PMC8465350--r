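locus	n_alleles_total
A3	3
A5	5
A17	7
A25	5
A51	9
A74	10
A80	7
A83	10
A87	8
A101	16
A103	13
A126	10
A149	11
A154	6
A156	8
A160	11
A177	12
A187	9
A191	21
A192	7
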