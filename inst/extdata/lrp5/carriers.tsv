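id	variant	acmg	age	bmd_l	t_l	z_l	bmd_th	t_th	z_th	carrier
11938	p.V99L	LP	55	0.90	-2.6	-2.3	0.86	-1.6	-0.9	1
9620	p.G333S	VUS	29	0.84	-2.2	-2.2	0.95	-0.5	-0.5	1
8957	p.E341K	VUS	28	0.67	-3.8	-3.8	0.78	-1.6	-1.6	1
12639	p.T443M	VUS	45	0.85	-2.2	-2.1	1.10	0.5	0.6	1
7971	p.R1036Q	LP	31	0.87	-2.0	-2.0	0.98	-0.3	-0.3	1
12141	p.R1135C	VUS	38	0.74	-3.1	-3.1	0.61	-2.7	-2.7	1
12025	p.R1342P	VUS	43	0.86	-2.0	-2.0	0.94	-0.6	-0.5	1
11241	p.A1525V	B	43	0.86	-2.1	-2.0	0.81	-1.4	-1.2	1
3801	p.A1525V	B	34	0.81	-2.5	-2.5	0.91	-0.8	-0.7	1
10517	p.A1537V	VUS	48	0.81	-2.5	-2.4	1.04	0.0	0.3	1
12007	p.S1585L	VUS	36	0.71	-3.4	-3.4	0.75	-1.8	-1.7	1
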