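stratum	gene	all_case	all_ctrl	excl_case	excl_ctrl	loci_case	loci_ctrl
rare	BRWD1	58	29	38	16	39	22
rare	DNMT1	13	7	10	1	13	4
rare	DNMT3B	30	20	20	10	21	12
rare	NSUN3	5	1	5	1	4	1
rare	RNF17	28	18	21	8	21	11
rare	UBR2	43	24	15	9	19	14
rare	USP1	11	4	9	3	9	4
rare	USP26	9	2	8	1	9	2
rare_lowfreq	BRWD1	85	50	38	16	40	23
rare_lowfreq	BRDT	67	43	8	7	12	10
rare_lowfreq	DNMT1	13	7	10	1	13	4
rare_lowfreq	DNMT3B	30	20	20	10	21	12
rare_lowfreq	MTHFR	32	19	10	6	15	9
rare_lowfreq	NSUN3	5	1	5	1	4	1
rare_lowfreq	RNF17	98	88	21	8	23	13
rare_lowfreq	UBR2	43	24	15	9	19	14
rare_lowfreq	USP1	11	4	9	3	9	4
rare_lowfreq	USP26	9	2	8	1	9	2
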