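sample	source	size_lo	size_hi	deformation_max	brightness_lo	brightness_hi	area_ratio_max	ip	tp	enrichment_printed	discrepant
beads_115_135	table	115	135	NA	NA	NA	1.05	52.6	86.3	1.64	FALSE
beads_125_135	table	125	135	NA	NA	NA	1.05	26.8	87.7	3.39	TRUE
myeloid	table	53	120	0.15	NA	NA	1.08	36.0	96.7	2.68	FALSE
myeloid	text	50	100	0.12	NA	NA	1.08	36.0	96.7	2.6	FALSE
lymphocytes	table	25	45	0.1	NA	NA	1.08	18.0	92.0	5.11	FALSE
lymphocytes	text	23	45	0.1	NA	NA	1.08	18.0	92.0	5	FALSE
neutrophils	table	56	100	NA	100	115	1.08	30.8	96.7	3.13	FALSE
neutrophils	text	50	100	NA	100	115	1.08	30.8	96.7	3.1	FALSE
platelets	table	NA	20	NA	80	100	1.08	18.0	40.0	2.22	FALSE
platelets	text	NA	20	NA	80	110	1.08	18.0	40.0	2.2	FALSE
wbc	table	23	100	0.1	NA	NA	1.08	0.09	60.0	667	FALSE
hl60s4_conc	table	75	125	0.2	NA	NA	1.08	40.1	97.0	2.41	FALSE
kc167	table	25	77	0.15	NA	NA	1.08	24.1	94.1	4	FALSE
hl60s4_hela	table	100	200	0.15	NA	NA	1.08	59.4	91.5	1.54	FALSE
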