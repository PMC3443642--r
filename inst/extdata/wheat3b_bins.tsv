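bin_name	full_name	arm	frac_start	frac_end	n_markers	size_mb	size_pct	map_cR	map_cM	print_saturation	print_br	print_res_rh	print_co	print_res_gen	print_ratio
3BS3	3BS3-0.87-1.00	S	0.87	1.00	7	56.0	5.7	79.7	5.2	8.0	0.7	0.7	0.1	10.8	15.3
3BS8	3BS8-0.78-0.87	S	0.78	0.87	155	39.0	3.9	572.9	33.1	0.3	7.4	0.1	0.8	1.2	17.3
3BS9	3BS9-0.57-0.75	S	0.57	0.75	9	78.0	7.9	69.2	13.4	8.7	0.5	1.1	0.2	5.8	5.2
3BS2	3BS2-0.56-0.57	S	0.56	0.57	3	4.0	0.4	36.7	NA	1.3	4.6	0.1	NA	NA	NA
3BS1	3BS1-0.33-0.55	S	0.33	0.55	44	95.0	9.6	113.7	1.6	2.2	0.6	0.8	0.0	61.3	73.4
C-3BS1	C-3BS1-0.33	S	0.00	0.33	28	142.0	14.3	115.6	0.9	5.1	0.4	1.2	0.0	167.1	136.0
C-3BL2	C-3BL2-0.22	L	0.00	0.22	27	124.0	12.5	99.1	1.6	4.6	0.4	1.3	0.0	80.0	63.9
3BL2	3BL2-0.22-0.28	L	0.22	0.28	29	33.0	3.3	58.9	1.6	1.1	0.9	0.6	0.0	21.3	38.0
3BL1	3BL1-0.31-0.50	L	0.31	0.50	47	39.0	3.9	37.0	6.2	0.8	0.5	1.1	0.2	6.3	6.0
3BL10	3BL10-0.50-0.63	L	0.50	0.63	4	73.0	7.4	41.3	3.5	18.3	0.3	1.8	0.0	21.2	12.0
3BL7	3BL7-0.63-1.00	L	0.63	1.00	187	208.0	21.0	459.6	104.2	1.1	1.1	0.5	0.5	2.0	4.4
Chr	Chr	NA	NA	NA	540	992.0	89.8	1871.9	179.0	1.8	1.0	0.5	0.2	5.5	10.45
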