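# Clinical covariates of the modeled induction-chemotherapy cohort (44 male oropharyngeal HNSCC patients).
# Columns: patient_id, response (CCR/NR), regimen (PF/T1PF/T2PF), hpv, cigarettes_per_day,
# alcohol_label (ordinal, as recorded), alcohol_l_per_day (midpoint encoding via parse_alcohol),
# hemoglobin (g/dL), age (years), study (MA and/or TLDA arm), status (alive/deceased at follow-up).
# NOTE: per-patient HPV status is SYNTHETIC - only the group totals are published
# (microarray arm: NR 3 positive / 7 negative; CCR 10 positive / 2 negative / 1 not ascertained).
patient_id	response	regimen	hpv	cigarettes_per_day	alcohol_label	alcohol_l_per_day	hemoglobin	age	study	status
23	CCR	PF	unknown	40	>1	1.5	12.1	63	MA	A
40	CCR	PF	positive	50	<1	0.5	15.1	45	MA/TLDA	A
57	CCR	PF	positive	40	>2	2.5	14.4	44	MA/TLDA	A
109	CCR	PF	positive	40	1	1	13.3	60	MA/TLDA	A
110	CCR	PF	positive	45	<1	0.5	12.8	56	MA/TLDA	A
121	CCR	PF	positive	45	>2	2.5	12.8	44	MA/TLDA	D
130	CCR	PF	positive	45	3	3	12.1	44	MA/TLDA	D
156	CCR	PF	positive	40	>3	3.5	12.7	56	MA/TLDA	D
157	CCR	PF	positive	0	0	0	11.1	71	MA/TLDA	A
164	CCR	PF	positive	20	0	0	11.4	60	MA/TLDA	A
169	CCR	PF	positive	65	1	1	12.7	58	MA/TLDA	A
195	CCR	PF	negative	30	1	1	12.1	47	MA/TLDA	A
219	CCR	PF	negative	40	1	1	12.1	52	MA/TLDA	A
48	NR	PF	positive	55	>2	2.5	11.1	55	MA/TLDA	D
140	NR	PF	positive	10	1	1	12.1	50	MA/TLDA	A
143	NR	PF	positive	20	1	1	13.1	62	MA/TLDA	A
159	NR	PF	negative	10	1	1	12.1	58	MA/TLDA	A
198	NR	PF	negative	20	1	1	12.1	63	MA/TLDA	D
210	NR	PF	negative	10	2	2	11.4	59	MA/TLDA	A
223	NR	PF	negative	40	2	2	11.9	65	MA/TLDA	D
246	NR	PF	negative	30	2	2	12.9	66	MA/TLDA	D
302	NR	PF	negative	40	>2	2.5	12.1	69	MA/TLDA	D
303	NR	PF	negative	20	>2	2.5	12.9	58	MA/TLDA	A
27	NR	PF	unknown	20	>2	2.5	12.8	50	TLDA	D
39	NR	PF	unknown	15	1	1	12.1	43	TLDA	A
76	NR	PF	unknown	0	<1	0.5	14.1	48	TLDA	D
318	NR	PF	unknown	60	>2	2.5	11.1	62	TLDA	D
329	NR	PF	unknown	40	>1	1.5	12.2	49	TLDA	A
310	CCR	T1PF	unknown	90	>2	2.5	11.2	58	TLDA	A
323	CCR	T1PF	unknown	10	<1	0.5	12.5	45	TLDA	A
353	CCR	T1PF	unknown	25	>1	1.5	11.5	52	TLDA	D
374	CCR	T1PF	unknown	35	>1	1.5	12	62	TLDA	D
138	NR	T1PF	unknown	20	1	1	11.2	54	TLDA	A
162	NR	T1PF	unknown	25	>2	2.5	10.8	58	TLDA	D
174	NR	T1PF	unknown	30	1	1	11.5	47	TLDA	D
350	NR	T1PF	unknown	30	1	1	11.6	69	TLDA	D
387	CCR	T2PF	unknown	20	1	1	11.5	53	TLDA	A
395	CCR	T2PF	unknown	10	1	1	12.1	61	TLDA	A
413	CCR	T2PF	unknown	10	1	1	11.5	64	TLDA	A
416	CCR	T2PF	unknown	20	1	1	12.1	62	TLDA	A
417	CCR	T2PF	unknown	15	2	2	12.1	65	TLDA	A
419	CCR	T2PF	unknown	10	0	0	12.1	51	TLDA	A
213	NR	T2PF	unknown	40	3	3	12	50	TLDA	D
427	NR	T2PF	unknown	20	1	1	11.5	55	TLDA	A
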