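gene	type	position	alt_aa	splice_impact	classification
HRAS	missense	58	I	.	P
HRAS	missense	12	V	.	P
HRAS	missense	12	S	.	P
KRAS	missense	60	G	.	P
PTPN11	missense	308	D	.	P
PTPN11	missense	308	S	.	LP
BRAF	missense	600	E	.	P
BRAF	splice	487	.	exon12_skip_out_of_frame	P
SOS1	missense	266	K	.	P
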