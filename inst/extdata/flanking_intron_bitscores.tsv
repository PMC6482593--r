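gene	db_id	pident	evalue	bitscore	group
PARD3B	NA	98.44	0	4617	up_increased
SIPA1L3	hsa_circ_10577	90.24	0	374	up_increased
FUT8	hsa_circ_02544	93.17	0	429	down_increased
RELL1	hsa_circ_08846	88.03	0	335	down_increased
FNDC3B	hsa_circ_15231	84.59	0	311	down_increased
PCNXL2	hsa_circ_10712	98.65	0	525	up_unchanged
RUNX1T1	hsa_circ_02162	89.74	0	427	up_unchanged
DOCK1	hsa_circ_00689	89.61	0	387	up_unchanged
TTC28	hsa_circ_22261	89.6	0	375	up_unchanged
ATXN1	hsa_circ_13397	89.45	0	300	up_unchanged
XXYLT1	hsa_circ_02143	89.26	0	521	up_unchanged
ECSIT	hsa_circ_00599	88.63	0	361	up_unchanged
CUX1	hsa_circ_12403	87.25	0	333	up_unchanged
EVI5	hsa_circ_11187	86.53	0	363	up_unchanged
SMURF2	hsa_circ_01208	86.23	0	324	up_unchanged
IQGAP1	hsa_circ_10932	86.13	0	291	up_unchanged
TEX2	hsa_circ_31354	85.26	0	316	up_unchanged
TBC1D8	hsa_circ_32540	84.04	0	263	up_unchanged
TPST1	hsa_circ_22617	83.83	0	560	up_unchanged
LZIC	hsa_circ_31394	83.55	0	278	up_unchanged
SCAF8	hsa_circ_06913	83.05	0	261	up_unchanged
KANSL1L	hsa_circ_06859	82.95	0	191	up_unchanged
VRK1	hsa_circ_08594	82.95	0	115	up_unchanged
DNAAF5	NA	82.87	0	254	up_unchanged
PDS5A	hsa_circ_29001	82.68	0	257	up_unchanged
PPP6R2	hsa_circ_07544	82.34	0	499	up_unchanged
ACVR2A	hsa_circ_04751	81.88	0	255	up_unchanged
VAMP3	hsa_circ_18051	81.76	0	250	up_unchanged
PRKY	hsa_circ_30664	81.66	0	230	up_unchanged
CSNK1G3	hsa_circ_08140	80.89	0	226	up_unchanged
PVT1	hsa_circ_16350	76.23	0	619	up_unchanged
FAM13B	hsa_circ_11413	89.9	0	379	down_unchanged
SCMH1	hsa_circ_12377	89.74	0	387	down_unchanged
N4BP2L2	hsa_circ_12240	88.45	0	363	down_unchanged
ADAMTS6	hsa_circ_28538	88.41	0	353	down_unchanged
PSD3	hsa_circ_02851	87.66	0	351	down_unchanged
UBAP2	hsa_circ_30156	87.63	0	326	down_unchanged
PTK2	hsa_circ_23485	85.49	0	396	down_unchanged
ASAP1	hsa_circ_09642	84.95	0	294	down_unchanged
MAN1A2	hsa_circ_02643	84.03	0	272	down_unchanged
EPHB4	hsa_circ_08510	82.08	0	257	down_unchanged
UGGT1	NA	87.2	0	326	up_decreased
RNF38	hsa_circ_32756	86.81	0	318	up_decreased
RNF138	hsa_circ_01057	86.3	0	315	up_decreased
SLF2	NA	85.76	0	315	up_decreased
RCAN3	hsa_circ_22201	83.84	0	278	up_decreased
PDS5B	hsa_circ_01546	82.06	0	254	up_decreased
RHOBTB3	hsa_circ_19124	90.64	0	392	down_decreased
ANKRD12	hsa_circ_31497	85.86	0	313	down_decreased
ANKRD17	hsa_circ_01636	85.37	0	296	down_decreased
CEP192	hsa_circ_26363	84.76	0	307	down_decreased
BMPR2	hsa_circ_06837	81.99	0	503	down_decreased
FGD4	hsa_circ_21030	78.65	0	115	down_decreased
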