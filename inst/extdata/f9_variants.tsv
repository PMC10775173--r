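gene	variant_class	nucleotide	protein	exon	domain	autopvs1	revel	spliceai	novel	activity	criteria	classification	n_patients	origin	severity	inhibitor	inconsistent	override_criteria	case_count	note
F9	missense	c.127C>T	p.Arg43Trp	2	Gla	-	0.692	-	Known	2.3/1.7	PS4-VS, PM1, PM2-PP, PP3, PP4	P	2	NA/NA	Moderate/Moderate	0/0				
F9	missense	c.128G>A	p.Arg43Gln	2	Gla	-	0.710	-	Known	<1	PS4-VS, PM1, PM2-PP, PP3, PP4	P	1	NA	Severe	0				
F9	missense	c.316G>A	p.Gly106Ser	4	EGF1	-	0.905	-	Known	8	PM1, PM2-PP, PP3-M, PP4, BS2	VUS	1	NA	Mild	0				
F9	missense	c.370G>A	p.Glu124Lys	4	EGF1	-	0.763	-	Known	3.2	PS4-M, PM1, PM2-PP, PP3, PP4	LP	1	NA	Moderate	0	yes	PS4-M, PM1, PM2-PP, PP3, PP4		REVEL 0.763 is in the moderate band but plain PP3 printed
F9	missense	c.509G>A	p.Cys170Tyr	5	EGF2	-	0.971	-	Known	<1	PS4-PP, PM1, PM2-PP, PP3-M, PP4	LP	1	NA	Severe	0				
F9	missense	c.571C>T	p.Arg191Cys	6	Linker	-	0.808	-	Known	<1/<1/<1/<1	PS4, PM1, PM2-PP, PP3-M, PP4	P	4	NA/NA/NA/NA	Severe/Severe/Severe/Severe	0/0/0/0				
F9	missense	c.754T>A	p.Cys252Ser	7	SP	-	0.978	-	Novel	NA	PM1, PM2-PP, PP3-M	VUS	1	M	?	NA				
F9	missense	c.781T>C	p.Trp261Arg	7	SP	-	0.910	-	Known	0.9	PS4-M, PM1, PM2-PP, PP3-M, PP4	LP	1	NA	Severe	NA				
F9	missense	c.934T>G	p.Tyr312Asp	8	SP	-	0.840	-	Known	<1	PS4-PP, PM1, PM2-PP, PP3-M, PP4	LP	1	NA	Severe	0				
F9	missense	c.992T>A	p.Val331Asp	8	SP	-	0.816	-	Novel	1.8	PM1, PM2-PP, PP3-M, PP4	LP	1	NA	Moderate	NA				
F9	missense	c.1115T>A	p.Leu372His	8	SP	-	0.837	-	Novel	1.9/3	PM1, PM2-PP, PP3-PM, PP4	LP	2	NA/NA	Moderate/Moderate	0/0				printed suffix PP3-PM read as moderate
F9	missense	c.1187G>A	p.Cys396Tyr	8	SP	-	0.959	-	Known	<1	PS4-M, PM1, PM2-PP, PP3-M, PP4	LP	1	NA	Severe	0				
F9	missense	c.1220G>A	p.Cys407Tyr	8	SP	-	0.949	-	Known	0.3	PS4-PP, PM1, PM2-PP, PP3-M, PP4	LP	1	M	Severe	0				
F9	missense	c.1295G>T	p.Gly432Val	8	SP	-	0.933	-	Known	<1	PS4, PM1, PM2-PP, PP3-M, PP4	P	1	M	Severe	0				
F9	missense	c.1328T>C	p.Ile443Thr	8	SP	-	0.905	-	Known	2.2	PS4-M, PM1, PM2-PP, PP3-M, PP4	LP	1	NA	Moderate	0				
F9	missense	c.1346G>A	p.Arg449Gln	8	Signal peptide	-	0.588	-	Known	17.7	PM1, PM2-PP, PP3, PP4, BS2	VUS	1	NA	Mild	NA	yes	PM1, PM2-PP, PP3, PP4, BS2		printed domain 'Signal peptide' inconsistent with residue 449 (SP domain); REVEL 0.588 outside all bands yet PP3 printed
F9	nonsense	c.223C>T	p.Arg75*	2	Gla	Very Strong	-	-	Known	0.1	PVS1, PS4, PM2-PP, PP4	P	1	NA	Severe	0.6				
F9	nonsense	c.880C>T	p.Arg294*	7	SP	Strong	-	-	Known	<1/<1	PVS1-S, PS4, PM2-PP, PP4	P	2	NA/NA	Severe/Severe	0/0				
F9	indel	c.252delA	p.Thr85Leufs*19	2	Gla	Very Strong	-	-	Novel	0.1	PVS1, PM2-PP, PP4	P	1	NA	Severe	0				
F9	gross_deletion	Exon 6-7 deletion	?	6-7	-	-	-	-	Novel	<1	PVS1, PM2-PP, PP4	P	1	NA	Severe	0				
F9	gross_deletion	Exon 7-8 deletion	?	7-8	-	-	-	-	Known	<1	PVS1, PS4, PM2-PP, PP4	P	1	NA	Severe	1.3				
F9	noncanonical_splice	c.252 + 3_c.252+6delGAGT	?	-	-	-	-	0.73	Known	<1	PM2-PP, PS4-M, PP3, PP4	VUS	1	NA	Severe	NA				
F9	noncanonical_splice	c.253-6T>G	?	-	-	-	-	0.36	Novel	6	PM2-PP, PP3, PP4	VUS	1	M	Mild	0				
F9	canonical_splice	c.723 + 1G>T	?	-	-	Very Strong	-	-	Known	<1	PVS1, PS4-M, PM2-PP, PP4	P	1	NA	Severe	0				
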