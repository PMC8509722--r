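# Reconstructed evidence contexts for the ten LRP5 variants. The published
# analysis reports only the aggregated odd scores and priors; these per-flag
# binarizations are a documented reconstruction consistent with the reported
# narrative (domain localization, motif context, ClinVar/dbSNP status) and
# reproduce the published odd scores and prior odds ratios. Synthetic in the
# sense that they were not printed by the source study.
variant	literature_pathogenic	dbsnp_low_freq_no_functional	prior_annotation_in_db	in_functional_domain	in_structured_domain	on_linear_motif	conserved_position	low_complexity_context
p.V99L	0	0	0	0	0	0	0	0
p.G333S	0	0	0	0	0	0	0	0
p.E341K	0	0	1	1	1	0	0	0
p.T443M	0	0	1	1	1	0	0	0
p.R1036Q	0	1	1	1	1	1	1	0
p.R1135C	0	1	1	1	1	1	1	0
p.R1342P	0	0	1	0	0	1	1	0
p.A1525V	0	1	1	0	0	1	1	0
p.A1537V	0	0	1	0	0	1	1	0
p.S1585L	0	0	0	0	0	1	0	0
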