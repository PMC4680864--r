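GLYCO	glycolysis-like toy set	P01	P08	P11	P14	P19
ADHES	adhesion-like toy set	P02	P09	P16	P20
HOUSE	housekeeping toy set	P03	P07	P12	P13	P15	P17	P18
NUCL	nuclear toy set	P01	P14	P11
ABSENT	members not quantified	QX1	QX2
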