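patient_id	group	chrom	start	end	ref	alt	gene	aa_change	vaf_pct_rel	vaf_pct_rem	vaf_pct_dx	found_at_diagnosis	coverage_ultradeep	vaf_pct_ultradeep
103L	npm1_loss	chr11	32417907	32417907	-	CCGA	WT1	A382fs	13.54	0	0	NO	9660	0
103L	npm1_loss	chr1	115258744	115258744	C	T	NRAS	G13D	31.89	0.45	0	NO	8062	0
103L	npm1_loss	chr2	25463286	25463286	C	T	DNMT3A	R736H	25	37	51.35	YES	11282	9.8
172L	npm1_loss	chr12	112888211	112888211	A	C	PTPN11	E76A	14.29	0	0	NO	5244	0
172L	npm1_loss	chr21	36171600	36171600	-	A	RUNX1	S322fs	50	0	0	NO	2207	0
172L	npm1_loss	chr2	25457243	25457243	G	A	DNMT3A	R882C	38.46	36	38.46	YES	4531	48.5
172L	npm1_loss	chr1	115258744	115258744	C	T	NRAS	G13D	8	0	0	NO	9311	0
355L	npm1_loss	chr7	140476755	140476755	T	C	BRAF	I551V	26.47	0	0	NO	2282	0
355L	npm1_loss	chr2	25458596	25458596	T	A	DNMT3A	L859F	35.29	0	0	NO	1163	0
355L	npm1_loss	chr17	29662024	29662024	-	A	NF1	A1994fs	36.54	0	0	NO	3309	0
355L	npm1_loss	chr2	209113113	209113113	G	T	IDH1	R132S	40	33	43	YES	2736	45.1
355L	npm1_loss	chr2	25468187	25468187	A	C	DNMT3A	C497G	29.27	25	48.08	YES	646	44.8
340P	npm1_persistent	chr2	25457242	25457242	C	T	DNMT3A	R882H	11	7	50	YES	1172	57.3
340P	npm1_persistent	chr5	170837543	170837543	-	TCTG	NPM1	L287fs	40	0	nd	YES	698	36.5
340P	npm1_persistent	chr13	28608244	28608244	-	TCCCATTTGAGATCATATTCATATTCTCTGAAATCAACGTAG	FLT3	E604ins	nd	0	nd	YES	1088	41.9
340P	npm1_persistent	chr17	7577548	7577548	C	T	TP53	G206S	61.9	0	0	YES	5151	0.6
340P	npm1_persistent	chr11	32417914	32417914	-	T	WT1	R380fs	50.5	30	32.14	YES	6096	38.9
584P	npm1_persistent	chr5	170837543	170837543	-	TCTG	NPM1	L287fs	nd	0	nd	YES	553	40.3
584P	npm1_persistent	chr2	25457252	25457252	T	C	DNMT3A	N879D	20	37	47.62	YES	1133	62.5
584P	npm1_persistent	chr2	209113112	209113112	C	T	IDH1	R132H	31.94	0	0	NO	3550	0
584P	npm1_persistent	chr4	55599321	55599321	A	T	KIT	D816V	30.9	0	0	NO	16031	0
1019P	npm1_persistent	chr5	170837545	170837545	-	TCTG	NPM1	L287fs	nd	0	nd	YES	423	21.7
1019P	npm1_persistent	chr2	25457242	25457242	C	T	DNMT3A	R882H	68.75	0	66.67	YES	862	49.4
1019P	npm1_persistent	chr2	209113112	209113112	C	T	IDH1	R132H	45.45	0	0	YES	4553	0.2
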