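variant	polyphen	sift	pmut	ddg
p.V99L	benign	tolerated	neutral	-0.44734934
p.G333S	benign	tolerated	neutral	-1.3066037
p.E341K	benign	tolerated	disease	-0.82809476
p.T443M	probably_damaging	tolerated	neutral	-0.26659723
p.R1036Q	possibly_damaging	tolerated	neutral	-1.171288
p.R1135C	probably_damaging	tolerated	disease	-0.47636602
p.R1342P	probably_damaging	tolerated	disease	-0.94002976
p.A1525V	benign	tolerated	neutral	-0.35033282
p.A1537V	benign	not_tolerated	neutral	-0.31014871
p.S1585L	probably_damaging	not_tolerated	disease	-0.30474209
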