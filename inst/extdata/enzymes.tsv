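name	recognition	cut_top	cut_bottom
NotI	GCGGCCGC	2	6
HindIII	AAGCTT	1	5
XhoI	CTCGAG	1	5
EcoRI	GAATTC	1	5
BamHI	GGATCC	1	5
AscI	GGCGCGCC	2	6
MluI	ACGCGT	1	5
BglII	AGATCT	1	5
SnaBI	TACGTA	3	3
EcoRV	GATATC	3	3
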