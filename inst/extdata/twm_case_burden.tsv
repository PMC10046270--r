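case_id	total_mutations	pathogenic_per_exome	wgs_tmb_per_mb	uv_band	msi	n_cnv	loh_percent	hrd_band
case1	85846	53	25.8	predominant	MSS	3	0	none
case2	2576	4	0.8	minor	MSS	247	53.6	none
case3	28148	27	8.5	predominant	MSS	2	0	none
case4	41635	24	12.4	predominant	MSS	71	4.1	none
case5	35410	27	10.6	predominant	MSS	152	28.4	minor
case6	293162	189	88.8	predominant	MSS	99	21.1	none
case7	539258	315	163.3	predominant	MSS	73	4.4	none
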