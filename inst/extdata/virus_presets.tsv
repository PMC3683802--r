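name	t_number	inradius_nm	arm_length	arm_net_charge	genome_nt	leq_bp_model	occupied_volume_fraction
PaV	3	13.0	48	13	4322	4766	0.074
CCMV	3	11.5	48	10	3233	3136	0.099
BMV	3	11.5	44	9	3233	3087	0.093
PC2	1	8.0	43	22	1767	1672	0.265
STNV	1	7.7	28	16	1239	1242	0.240
BBT	1	7.5	27	12	1066	1058	0.209
STMV	1	7.2	19	11	1058	922	0.232
SPMV	1	6.8	20	13	826	918	0.276
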