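CHR	BP	SNP	GENE	A1	A2	FRQ_A1	OR_DISC	L95_DISC	U95_DISC	P_DISC	OR_FU	L95_FU	U95_FU	P_FU	OR_OVERALL	L95_OVERALL	U95_OVERALL	P_OVERALL	GROUP
2	37515958	rs876461	PRKD3/NDUFAF7	A	G	0.143	1.07	1.04	1.09	9.14e-7	1.08	1.04	1.13	3.07e-4	1.07	1.05	1.09	1.34e-9	novel
8	145154222	rs34674752	SHARPIN	A	G	0.052	1.11	1.06	1.16	4.02e-6	1.20	1.10	1.31	1.65e-5	1.13	1.09	1.18	1.00e-9	novel
8	145158607	rs34173062	SHARPIN	A	G	0.085	1.16	1.11	1.21	1.33e-11	1.09	1.02	1.17	7.35e-3	1.14	1.10	1.18	9.62e-13	novel
16	81900853	rs3935877	PLCG2	C	T	0.868	0.92	0.90	0.95	1.12e-7	0.92	0.85	0.99	1.96e-2	0.92	0.90	0.95	6.85e-9	novel
17	4805437	rs72835061	CHRNE	A	C	0.085	1.09	1.06	1.12	3.92e-9	1.07	1.02	1.12	7.83e-3	1.09	1.06	1.11	1.51e-10	novel
21	27473875	rs2154481	APP	C	T	0.483	0.95	0.93	0.96	9.26e-10	0.96	0.93	0.99	3.31e-3	0.95	0.94	0.96	1.39e-11	novel
4	11027619	rs4351014	HS3ST1	C	T	0.684	0.94	0.92	0.96	5.37e-10	0.93	0.88	0.98	4.54e-3	0.94	0.92	0.95	9.16e-12	known
16	70694000	rs4985556	IL34	A	C	0.111	1.08	1.05	1.11	2.28e-8	1.09	1.03	1.16	4.59e-3	1.08	1.06	1.11	3.91e-10	known
16	81773209	rs12444183	PLCG2	A	G	0.407	0.95	0.93	0.97	1.48e-8	0.92	0.88	0.96	3.23e-5	0.95	0.93	0.96	6.81e-12	known
14	106195719	rs7153315	ELK2AP	C	G	0.750	0.94	0.92	0.96	9.80e-8	1.16	1.01	1.33	4.12e-2	0.94	0.92	0.97	9.04e-7	suggestive
15	51002342	rs76523702	SPPL2A	C	T	0.802	1.06	1.04	1.08	6.86e-8	1.02	0.97	1.07	3.501e-1	1.05	1.03	1.08	1.08e-7	suggestive
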