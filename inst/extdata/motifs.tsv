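name	consensus	max_mismatches
Sp1	GGGGCGGGGC	1
Oct-1A	ATGCAAAT	1
C/EBPalp	TTGCGCAA	1
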