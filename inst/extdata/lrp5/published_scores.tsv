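variant	prediction_score	odd_score	merged_score	prior_or	posterior_or	posterior_or_pct	meaning	class
p.V99L	1	1	2	1	2	22.22	LN	2
p.G333S	1	1	2	1	2	22.22	LN	2
p.E341K	2	3	5	1	5	55.56	LP	4
p.T443M	2	3	5	1	5	55.56	LP	4
p.R1036Q	2	5	7	1.25	8.745	97.22	P	5
p.R1135C	2	5	8	1.25	10	111.11	P	5
p.R1342P	3	3	6	1	6	66.67	LP	4
p.A1525V	2	3	5	1.25	6.25	69.44	LP	4
p.A1537V	2	3	5	1	5	55.56	LP	4
p.S1585L	4	1	5	1	5	55.56	LP	4
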