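gene_id	mrna_log2fc
P01	2.0
P02	-1.8
P03	0.1
P07	-0.2
P08	0.3
P09	-0.5
P11	0.2
P14	-1.5
P16	1.4
P20	-2.2
MX1	3.0
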