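protein_id	mw_da	2i_1	2i_2	2i_3	serum_1	serum_2	serum_3
P01	55562.7	40	45	50	5	6	7
P02	33337.62	3	4	5	30	28	35
P03	111125.4	20	22	18	21	19	23
P04	44450.16	1	1	1	0	0	0
P05	22225.08	5	5	0	0	0	4
P06	66675.24	2	2	1	0	0	0
P07	88900.32	12	14	13	12	15	11
P08	27781.35	60	55	65	58	62	57
P09	50006.43	8	9	7	16	18	20
P10	38893.89	0	1	0	2	2	1
P11	61119.0	25	30	28	27	26	29
P12	47783.92	10	12	9	11	10	13
P13	72231.51	6	5	7	6	7	5
P14	29447.23	33	35	31	14	15	16
P15	90011.57	4	5	6	5	4	6
P16	41116.4	18	16	17	36	40	38
P17	58340.84	9	8	10	9	10	8
P18	35560.13	7	6	8	7	8	6
P19	100012.86	15	17	16	15	16	17
P20	24447.59	11	10	12	23	25	24
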