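sample	method	genotype_calls	examined	tp	fp	fn	reported_precision	reported_recall	reported_f
NA18943	IMSindel	60	54	49	5	14	0.91	0.78	0.84
NA18943	GATK	39	30	26	4	37	0.87	0.41	0.56
NA18943	PINDEL	70	60	32	28	31	0.53	0.51	0.52
NA18943	ScanIndel	32	24	20	4	43	0.83	0.32	0.46
NA18948	IMSindel	47	36	32	4	22	0.89	0.59	0.71
NA18948	GATK	17	15	15	0	39	1.00	0.28	0.43
NA18948	PINDEL	65	49	30	19	24	0.61	0.56	0.58
NA18948	ScanIndel	40	27	19	8	35	0.70	0.35	0.39
NA12878	IMSindel	17	NA	16	1	8	0.94	0.67	0.78
NA12878	GATK	15	NA	7	8	17	0.47	0.29	0.36
NA12878	PINDEL	22	NA	14	8	10	0.64	0.58	0.61
NA12878	ScanIndel	19	NA	10	9	14	0.53	0.42	0.47
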