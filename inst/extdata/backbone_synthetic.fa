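>backbone_synthetic_280bp spacer backbone with embedded amplification-primer sites
GATCTTAACCCTCACTAAAGGGAGGCTAAGATTGTTAAAATGTTTTCGAGAAACCACCAT
CTAACTCTAAGGCCATATACCTTCGCCCACTACAATTTCGACAGAGCGCTGGTTGCACGG
GTGTGACATGGGTCGTCTCAGAGTGTGCACAGAGACAAAAGGTTACATCAATCACAGTTT
GACCATGGAGTGATCACACTTTTCTCCTTAACCCCTAAAGATGATTCGGCCCTGGCAATG
TCAGTAGGGTACCGCCTATAGTGTCACCTAAATTGGGATC
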