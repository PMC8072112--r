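mouse_id	parental_mouse_id	is_allotransplant	genotype	tissue	v_subgroup	v_call_imgt	v_call_vbase2	d_subgroup	d_call	j_call	shm_percent	mutation_status	colony_count	sample_total	percent_printed	cdr3_aa	cdr3_length	pI
13		FALSE	+/+	spleen	VH14	IGHV14-2*02	VHSM7.a2psi.88	D2	DSP2.9	JH4	1.1	UM	5	13	38	GRDDGYYYAMDY	12	3.93
13		FALSE	+/+	spleen	VH5	IGHV5-17*02	VH7183.a47.76	D3	DST4.3	JH4	2.1	M	3	13	23	AREGPRRDYYAMDY	14	6.16
16		FALSE	+/+	spleen	VH1	IGHV1-85*01	VHJ558.88.194	D1	DFL16.1	JH3	0.35	UM	6	10	60	ASYAFAY	7	5.57
16		FALSE	+/+	spleen	VH5	IGHV5-17*02	VH7183.a47.76	D2	DSP2.2	JH4	0.35	UM	3	10	30	ASRSTMIIMDY	11	5.88
16		FALSE	+/+	blood	VH5	IGHV5-17*02	VH7183.a47.76	D2	DSP2.2	JH4	0.35	UM	7	10	70	ASRSTMIIMDY	11	5.88
16		FALSE	+/+	blood	VH1	IGHV1-85*01	VHJ558.88.194	D1	DFL16.1	JH3	0.7	UM	3	10	30	ASYAFAY	7	5.57
29		FALSE	+/+	spleen	VH1	IGHV1-80*01	VHJ558.83.189	D2	DSP2.2	JH4	2.1	M	8	10	80	ASPSYDYPYYYAMDY	15	3.56
40		FALSE	+/+	spleen	VH5	IGHV5-17*02	VH7183.a47.76	D2	DSP2.6	JH4	0	UM	8	10	80	ATYYGYDRVYYYAMDY	16	4.21
40		FALSE	+/+	blood	VH5	IGHV5-17*02	VH7183.a47.76	D2	DSP2.6	JH4	0.35	UM	9	10	90	ATYYGYDRVYYYAMDY	16	4.21
45		FALSE	+/+	spleen	VH1	IGHV1-9*01	VHJ558.b9	D2	DSP2.2	JH3	0.7	UM	8	10	80	ARGDYDGEFAY	11	4.03
50		FALSE	+/+	spleen	VH1	IGHV1-74*04	V102	D2	DSP2.4	JH4	0.35	UM	10	10	100	ASGYDYAMDY	10	3.56
51		FALSE	+/+	spleen	VH1	IGHV1-9*01	VHJ558.b9	D4	DQ52	JH4	0.7	UM	10	10	100	ARGNWDFYYAMDY	13	4.21
55		FALSE	+/+	spleen	VH1	IGHV1-74*04	V102	D2	DSP2.4	JH4	0	UM	10	10	100	ASGYDYAMDY	10	3.56
55		FALSE	+/+	blood	VH5	IGHV5-17*02	VH7183.a47.76	D2	DSP2.9	JH4	0.35	UM	5	10	50	AVYVIYDGYYGAMDY	15	3.56
55		FALSE	+/+	blood	VH1	IGHV1-77*01	VHJ558.80.186	D1	DFL16.1e	JH2	1.4	UM	5	10	50	ARGGDY	6	5.88
55F1	55	TRUE	+/+	node	VH1	IGHV1-77*01	VHJ558.80.186	D1	DFL16.1e	JH2	0.7	UM	9	10	90	ARGGDY	6	5.88
65		FALSE	+/+	spleen	VH5	IGHV5-17*02	VH7183.a47.76	D3	DST4.3	JH2	0	UM	2	9	22.2	ALGAGYFDY	9	3.8
65		FALSE	+/+	spleen	VH1	IGHV1-69*02	VH124	D2	DSP2.9	JH1	4.9	M	2	9	22.2	ARGNDGSYWYFDV	13	4.21
65		FALSE	+/+	spleen	VH3	IGHV3-5*02	VH36-60.a5.112	D3	DST4	JH4	1.0	UM	2	9	22.2	ARIRGGAMDY	10	8.79
65		FALSE	+/+	blood	VH14	IGHV14-2*02	VHSM7.a2psi.88	D2	DSP2.9	JH4	0.35	UM	3	10	30	GRDDGYYYAMDY	12	3.93
65		FALSE	+/+	blood	VH5	IGHV5-17*02	VH7183.a47.76	D3	DST4.3	JH2	0.7	UM	7	10	70	ALGAGYFDY	9	3.8
72		FALSE	+/+	spleen	VH14	IGHV14-2*02	VHSM7.a2psi.88	D2	DSP2.9	JH4	0.7	UM	4	14	29	GRDDGYYYAMDY	12	3.93
72		FALSE	+/+	spleen	VH1	IGHV1S130*01	Unknown	D2	DSP2.2	JH2	0.35	UM	4	14	29	ARVRNWDFEDY	11	4.56
72F1	72	TRUE	+/+	spleen	VH1	IGHV1S130*01	Unknown	D2	DSP2.2	JH2	0	UM	7	10	70	ARVRNWDFEDY	11	4.56
74		FALSE	+/+	spleen	VH1	IGHV1S130*01	Unknown	D1	DFL16.1	JH2	0	UM	6	10	60	ASGPDFDY	8	3.56
74		FALSE	+/+	spleen	VH1	IGHV1-9*01	VHJ558.b9	D2	DSP2.4	JH4	0	UM	3	10	30	ARGGYYGYDGDYYAMDY	17	3.93
74F1	74	TRUE	+/+	spleen	VH1	IGHV1-9*01	VHJ558.b9	D2	DSP2.4	JH4	0.7	UM	8	8	100	ARGGYYGYDGDYYAMDY	17	3.93
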