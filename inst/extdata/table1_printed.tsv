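gene	variant_class	severe_n	severe_pct	moderate_n	moderate_pct	mild_n	mild_pct	unknown_n	unknown_pct	total_n	total_pct	inhibitor_positive	inhibitor_tested	inhibitor_pct	de_novo	inherited	n_variants	variants_pct	n_novel	flags
F8	IVS22_inversion	49	41.9	1	6.25	2	10.5	0	0	52	32.2	4	34	11.8	4	30	NA	NA	NA	moderate_pct;total_pct
F8	IVS1_inversion	3	2.6	0	0	1	5.3	0	0	4	2.5	0	3	0	0	4	NA	NA	NA	
F8	missense	13	11.1	12	75	11	57.9	4	44.4	40	24.8	0	32	0	0	24	36	43.4	5	
F8	nonsense	20	17.1	1	6.25	0	0	3	33.3	24	14.9	4	19	21	0	15	18	21.7	4	moderate_pct;inhibitor_pct
F8	indel	22	18.8	1	6.25	0	0	2	22.2	25	15.6	3	21	14.3	1	18	22	26.5	11	moderate_pct;total_pct
F8	gross_deletion	6	5.1	0	0	0	0	0	0	6	3.7	2	6	33.3	0	2	5	6	0	
F8	canonical_splice	2	1.7	0	0	0	0	0	0	2	1.3	1	2	50	0	1	2	2.4	0	total_pct
F8	none	2	1.7	1	6.25	5	26.3	0	0	8	5	0	0	0	0	0	0	0	0	moderate_pct;inhibitor_pct
F8	total	117	NA	16	NA	19	NA	9	NA	161	NA	14	117	11.9	5	94	83	NA	20	inhibitor_pct
F9	missense	11	55	7	100	2	50	1	100	21	65.6	0	17	0	0	3	16	66.7	3	
F9	nonsense	3	15	0	0	0	0	0	0	3	9.4	1	3	33.3	NA	NA	2	8.3	0	
F9	indel	1	5	0	0	0	0	0	0	1	3	0	1	0	NA	NA	1	4.2	1	total_pct
F9	gross_deletion	2	10	0	0	0	0	0	0	2	6.3	1	2	50	NA	NA	2	8.3	1	
F9	canonical_splice	1	5	0	0	0	0	0	0	1	3.1	0	1	0	0	0	1	4.2	0	
F9	noncanonical_splice	1	5	0	0	1	25	0	0	2	6.3	0	1	0	0	1	2	8.3	1	
F9	none	1	5	0	0	1	25	0	0	2	6.3	0	0	0	NA	NA	0	0	0	inhibitor_pct
F9	total	20	NA	7	NA	4	NA	1	NA	32	NA	2	25	8	0	4	24	NA	6	
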