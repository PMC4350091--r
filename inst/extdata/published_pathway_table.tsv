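pathway	n_sequenced	n_nominal	p_value	printed_fdr
Epigenetic genes	50	10	0.002	0.024
PI3 kinase pathway	11	3	0.01	0.06
GnRH signaling pathway	16	2	0.17	0.63
MAPK signaling pathway	26	3	0.26	0.63
Steroid hormone biosynthesis and metabolism	12	1	0.30	0.63
DNA repair or recombination	14	1	0.37	0.63
Cell cycle	14	1	0.37	0.63
Meiosis	19	1	0.53	0.73
Apoptosis	21	1	0.58	0.73
TGF signaling pathway	22	1	0.61	0.73
P53 signaling pathway	20	0	0.86	0.87
Wnt signaling pathway	21	0	0.87	0.87
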