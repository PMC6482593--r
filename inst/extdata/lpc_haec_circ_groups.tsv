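gene_id	gene	db_id	reads_lpc	reads_control	ratio	log2_ratio	fc_mrna	exon_indices	exon_count	exon_count_genomic	group
23094	SIPA1L3	hsa_circ_10577	9	2	4.5	2.17	1.12	11,12	2	24	up_increased
117583	PARD3B	NA	4	1	4	2	1.19	4,5,6,7,8,9,10,11,12,13,14,15	12	33	up_increased
116840	CNTROB	hsa_circ_09218	4	1	4	2	1.11	13	1	22	up_increased
2530	FUT8	hsa_circ_02544	1	7	0.14	-2.81	1.2	3	1	15	down_increased
768211	RELL1	hsa_circ_08846	2	15	0.13	-2.91	1.15	6,5,4	3	8	down_increased
51150	SDF4	hsa_circ_21644	1	9	0.11	-3.17	1.15	4,3	2	8	down_increased
64778	FNDC3B	hsa_circ_15231	1	15	0.07	-3.91	1.13	5,6	2	30	down_increased
55852	TEX2	hsa_circ_31354	15	1	15	3.91	0.98	7,6,5	3	15	up_unchanged
5820	PVT1	hsa_circ_16350	8	1	8	3	NA	2	1	9	up_unchanged
51232	CRIM1	hsa_circ_16396	15	2	7.5	2.91	1.03	2,3,4	3	22	up_unchanged
1793	DOCK1	hsa_circ_00689	7	1	7	2.81	1.05	2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23	22	56	up_unchanged
4670	HNRNPM	hsa_circ_20744	7	1	7	2.81	1.01	2,3,4,5	4	16	up_unchanged
22937	SCAP	hsa_circ_19380	7	1	7	2.81	0.94	8,7,6,5,4	5	25	up_unchanged
9341	VAMP3	hsa_circ_18051	7	1	7	2.81	0.94	3,4	2	5	up_unchanged
NA	RP11-146B14.1	NA	6	1	6	2.58	NA	12,13,14,15	4	NA	up_unchanged
9380	GRHPR	hsa_circ_03935	6	1	6	2.58	1.06	2,3,4	3	11	up_unchanged
27086	FOXP1	hsa_circ_19469	6	1	6	2.58	1.01	12,11,10,9,8	5	32	up_unchanged
64750	SMURF2	hsa_circ_01208	5	1	5	2.32	1.11	10,9,8,7,6	5	19	up_unchanged
84456	L3MBTL3	NA	5	1	5	2.32	1.03	4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21	18	30	up_unchanged
862	RUNX1T1	NA	5	1	5	2.32	0.99	5,4,3,2	4	20	up_unchanged
151050	KANSL1L	hsa_circ_06859	5	1	5	2.32	0.96	4,3,2	3	23	up_unchanged
11138	TBC1D8	hsa_circ_32540	5	1	5	2.32	0.94	15,14,13,12,11,10	6	25	up_unchanged
84328	LZIC	hsa_circ_31394	5	1	5	2.32	0.94	4,3,2	3	10	up_unchanged
23331	TTC28	hsa_circ_22261	5	1	5	2.32	0.93	3,2	2	29	up_unchanged
1456	CSNK1G3	hsa_circ_08140	14	3	4.67	2.22	0.93	2,3,4	3	18	up_unchanged
8460	TPST1	hsa_circ_22617	9	2	4.5	2.17	0.98	2,3	2	8	up_unchanged
NA	PRKY	hsa_circ_30664	4	1	4	2	NA	4,5,6,7	4	8	up_unchanged
NA	PCNXL2	hsa_circ_10712	4	1	4	2	NA	23,22	2	NA	up_unchanged
1523	CUX1	hsa_circ_12403	8	2	4	2	1.11	21	1	34	up_unchanged
9701	PPP6R2	hsa_circ_07544	4	1	4	2	1.11	2,3	2	29	up_unchanged
54919	DNAAF5	NA	4	1	4	2	1.1	9,10,11	3	14	up_unchanged
84293	FAM213A	NA	4	1	4	2	1.06	2,3,4	3	9	up_unchanged
7813	EVI5	hsa_circ_11187	4	1	4	2	1.04	19,18,17	3	30	up_unchanged
81608	FIP1L1	hsa_circ_18069	4	1	4	2	1.02	11,12,13	3	19	up_unchanged
51295	ECSIT	hsa_circ_00599	4	1	4	2	1	4,3	2	9	up_unchanged
152002	XXYLT1	hsa_circ_02143	4	1	4	2	1	3,2	2	11	up_unchanged
6310	ATXN1	hsa_circ_13397	4	1	4	2	0.99	8	1	11	up_unchanged
1024	CDK8	hsa_circ_27078	4	1	4	2	0.98	10,11,12	3	14	up_unchanged
6259	RYK	hsa_circ_26048	4	1	4	2	0.98	13,12,11,10,9,8,7	7	15	up_unchanged
92	ACVR2A	hsa_circ_04751	4	1	4	2	0.98	2,3,4	3	12	up_unchanged
22828	SCAF8	hsa_circ_06913	4	1	4	2	0.98	2,3,4,5,6	5	22	up_unchanged
29086	BABAM1	hsa_circ_04303	4	1	4	2	0.96	7,8	2	9	up_unchanged
23244	PDS5A	hsa_circ_29001	4	1	4	2	0.95	21,20,19,18,17	5	36	up_unchanged
7443	VRK1	hsa_circ_08594	4	1	4	2	0.94	2,3,4,5,6,7,8,9,10,11	10	15	up_unchanged
8826	IQGAP1	hsa_circ_10932	4	1	4	2	0.93	6,7,8,9	4	39	up_unchanged
23362	PSD3	hsa_circ_02851	1	7	0.14	-2.81	1.05	8,7,6,5	4	29	down_unchanged
55833	UBAP2	hsa_circ_30156	1	7	0.14	-2.81	0.94	12,11,10,9	4	30	down_unchanged
10443	N4BP2L2	hsa_circ_12240	1	7	0.14	-2.81	0.93	6,5,4,3	4	22	down_unchanged
6904	TBCD	hsa_circ_00754	2	15	0.13	-2.91	1.05	14,15,16,17,18,19	6	61	down_unchanged
5747	PTK2	hsa_circ_23485	2	15	0.13	-2.91	1.03	5,4,3	3	44	down_unchanged
23603	CORO1C	hsa_circ_01619	1	9	0.11	-3.17	1.06	8,7	2	20	down_unchanged
5917	RARS	hsa_circ_21209	1	9	0.11	-3.17	1.01	2,3,4,5	4	15	down_unchanged
11174	ADAMTS6	hsa_circ_28538	3	29	0.1	-3.27	1.05	7,6,5,4,3,2	6	33	down_unchanged
22955	SCMH1	hsa_circ_12377	1	10	0.1	-3.32	1.09	10,9	2	22	down_unchanged
51306	FAM13B	hsa_circ_11413	1	10	0.1	-3.32	1.01	10,9,8	3	30	down_unchanged
2050	EPHB4	hsa_circ_08510	1	10	0.1	-3.32	1	12,11	2	17	down_unchanged
444	ASPH	hsa_circ_10828	1	11	0.09	-3.46	1	3,2	2	33	down_unchanged
57488	ESYT2	hsa_circ_25060	1	11	0.09	-3.46	0.95	13,12,11,10,9	5	26	down_unchanged
10905	MAN1A2	hsa_circ_02643	1	15	0.07	-3.91	1.06	2,3,4,5	4	14	down_unchanged
50807	ASAP1	hsa_circ_09642	1	15	0.07	-3.91	0.93	14,13,12,11,10,9	6	37	down_unchanged
4649	MYO9A	NA	8	1	8	3	0.75	39,38,37,36,35,34,33,32,31,30,29,28	12	48	up_decreased
10564	ARFGEF2	NA	5	1	5	2.32	0.91	5,6,7	3	39	up_decreased
51444	RNF138	hsa_circ_01057	5	1	5	2.32	0.9	3,4	2	8	up_decreased
152006	RNF38	hsa_circ_32756	5	1	5	2.32	0.79	4,3	2	19	up_decreased
23047	PDS5B	hsa_circ_01546	4	1	4	2	0.91	2,3	2	38	up_decreased
55719	SLF2	NA	4	1	4	2	0.9	5,6	2	21	up_decreased
55247	NEIL3	hsa_circ_00262	4	1	4	2	0.84	8,9	2	10	up_decreased
56886	UGGT1	NA	4	1	4	2	0.78	2,3,4,5,6,7,8,9,10,11,12,13,14,15,16	15	44	up_decreased
23499	MACF1	NA	4	1	4	2	0.68	42,43,44,45,46,47,48,49,50,51,52	11	111	up_decreased
11123	RCAN3	hsa_circ_22201	4	1	4	2	0.67	2	1	7	up_decreased
659	BMPR2	hsa_circ_06837	1	7	0.14	-2.81	0.84	2,3	2	13	down_decreased
23253	ANKRD12	hsa_circ_31497	1	7	0.14	-2.81	0.78	2,3,4,5,6,7	6	18	down_decreased
10725	NFAT5	hsa_circ_16704	1	8	0.13	-3	0.64	15	1	19	down_decreased
26057	ANKRD17	hsa_circ_01636	1	9	0.11	-3.17	0.91	29	1	37	down_decreased
55125	CEP192	hsa_circ_26363	1	9	0.11	-3.17	0.85	2,3,4,5,6,7,8,9	8	46	down_decreased
121512	FGD4	hsa_circ_21030	1	9	0.11	-3.17	0.85	5,6,7,8,9,10	6	27	down_decreased
22836	RHOBTB3	hsa_circ_19124	1	17	0.06	-4.09	0.91	6,7	2	14	down_decreased
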