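component	variance_pct	gene	loading	expression_change
1	35.55	CAPN6	0.99	down
1	35.55	MYH1G	-0.98	up
1	35.55	TNNI1	-0.99	up
1	35.55	MB	-0.99	up
1	35.55	ACTN1	-0.99	up
2	24.51	HYAL1	0.88	up
2	24.51	MFN2	-0.95	down
2	24.51	MFN1	-0.97	down
2	24.51	AGRN	-0.97	down
2	24.51	CHRNA1	-0.98	down
3	9.04	PLEKHG5	0.84	up
3	9.04	DES	0.82	up
3	9.04	PVALB	0.80	up
3	9.04	SOX5	-0.72	down
3	9.04	CAPN10	-0.80	down
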