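dmr	chrom	start	end	nearest_gene	beta_twin	se_twin	p_twin	mz_diff_r	beta_unrel	se_unrel	p_unrel	r2_unrel	beta_ma_printed	se_ma_printed	p_ma_printed
TRPA1	8	73151000	73152000	TRPA1	-0.23	0.04	2.6e-6	-0.68	-0.40	0.07	1.3e-6	0.39	-0.28	0.04	1.2e-13
chr18	18	5039500	5040000	NA	-0.20	0.04	2.6e-6	-0.77	-0.27	0.09	3.2e-3	0.17	-0.21	0.03	4.1e-13
OR8B8	11	123833500	123834500	OR8B8	-0.26	0.04	2.3e-7	-0.85	-0.12	0.09	2.0e-1	0.03	-0.24	0.03	3.4e-12
ST6GALNAC3_1	1	76264000	76265000	ST6GALNAC3	-0.19	0.03	3.5e-6	-0.71	-0.28	0.08	1.6e-3	0.19	-0.20	0.03	4.4e-12
MTMR12	5	32273500	32274500	MTMR12	0.24	0.04	2.7e-5	0.77	0.34	0.08	8.4e-5	0.28	0.26	0.04	5.1e-12
chr4	4	165977000	165978000	NA	0.24	0.04	2.1e-7	0.79	0.12	0.09	2.1e-1	0.03	0.22	0.03	5.6e-12
MICAL2	11	12054000	12055000	MICAL2	-0.27	0.04	5.5e-8	-0.59	-0.22	0.09	1.4e-2	0.12	-0.26	0.04	7.2e-12
ST6GALNAC3_2	1	76264500	76265500	ST6GALNAC3	-0.18	0.03	5.3e-6	-0.68	-0.28	0.09	2.0e-3	0.18	-0.20	0.03	1.1e-11
NFU1	2	69530500	69531500	NFU1	-0.24	0.04	8.7e-7	-0.68	-0.32	0.08	2.3e-4	0.25	-0.26	0.04	1.1e-11
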