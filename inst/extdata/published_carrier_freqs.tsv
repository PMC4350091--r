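label	freq_case_pct	freq_ctrl_pct	n_case	n_ctrl	digits	printed_or	printed_p
BRWD1	7.27	4.09	757	709	2	1.84	0.01
USP26	1.19	0.28	757	709	2	4.25	0.07
epigenetic_set	22.5	13.7	757	709	1	NA	1.4e-05
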