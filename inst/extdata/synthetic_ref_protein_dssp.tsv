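chain	resno	class
A	1	Loop
A	2	Helix
A	3	Helix
A	4	Helix
A	5	Helix
A	6	Helix
A	7	Helix
A	8	Helix
A	9	Helix
A	10	Helix
A	11	Helix
A	12	Helix
A	13	Helix
A	14	Loop
A	21	Loop
A	22	Sheet
A	23	Sheet
A	24	Sheet
A	25	Sheet
A	26	Sheet
A	27	Sheet
A	28	Loop
A	39	Loop
A	40	Sheet
A	41	Sheet
A	42	Sheet
A	43	Sheet
A	44	Sheet
A	45	Sheet
A	46	Loop
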