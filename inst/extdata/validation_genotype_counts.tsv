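# validation-phase genotype distribution (published summary table); columns:
# gene, variant_id, n0=common homozygous, n1=heterozygous, n2=rare homozygous,
# maf_validation/maf_testing = printed two-decimal minor allele frequencies
gene	variant_id	n0	n1	n2	maf_validation	maf_testing
AKR7A2	rs1043657	660	136	6	0.09	0.10
TUBB1	rs10485828	521	252	27	0.19	0.21
MADD	rs10501320	428	318	51	0.26	0.28
RARB	rs1058378	666	134	2	0.09	0.09
SLC28A3	rs10868138	681	108	8	0.08	0.07
ABCB5	rs11983326	409	332	59	0.28	0.28
PIK3C2G	rs12312266	462	290	44	0.24	0.21
CYP4F12	rs12460651	683	111	8	0.08	0.12
RRAGD	rs1555403	432	318	48	0.26	0.24
GSTP1	rs1695	366	355	76	0.32	0.33
DPYD	rs17376848	724	76	2	0.05	0.06
DPYD	rs1801160	729	74	0	0.05	0.05
ABCA4	rs1801466	678	117	4	0.08	0.11
CYP2C9	rs1934969	281	387	135	0.41	0.39
AHRR	rs2013782	312	389	97	0.37	0.41
ABCB1	rs2032583	639	158	6	0.10	0.11
CYP2E1	rs2070677	626	164	9	0.11	0.14
CDA	rs2072671	360	366	66	0.31	0.36
PIP4K2B	rs2075061	301	383	119	0.39	0.40
BAK1	rs210134	398	335	62	0.29	0.25
ABCC1	rs212091	598	186	14	0.13	0.18
GSTA2	rs2180314	251	409	141	0.43	0.41
ATP7A	rs2227291	499	262	37	0.21	0.26
BIRC7	rs2273487	227	405	161	0.46	0.49
IRS1	rs2288587	735	59	3	0.04	0.06
KCNAB1	rs2293194	229	373	198	0.48	0.48
DPYD	rs2297595	617	169	16	0.13	0.15
CES1	rs2307240	699	72	1	0.05	0.07
CYP2E1	rs2515641	627	166	9	0.11	0.14
ENOSF1	rs2612083	332	370	101	0.36	0.38
DPYS	rs2669429	246	421	135	0.43	0.46
NR5A2	rs2816948	619	165	11	0.12	0.13
CYP2D6	rs28371725	672	112	11	0.08	0.06
ABCC6	rs2856585	719	80	2	0.05	0.06
ABCB8	rs3214587	636	159	7	0.11	0.12
SLCO1C1	rs34288910	597	186	19	0.14	0.14
ABCC1	rs3743527	476	278	46	0.23	0.21
AKT1	rs3803304	407	317	64	0.28	0.29
SLCO1A2	rs3834939	366	360	77	0.32	0.30
PPARG	rs3856806	592	181	26	0.15	0.12
GSTA1	rs3957357	260	412	124	0.41	0.41
UGT2A1	rs4148301	644	147	10	0.10	0.11
ABCC3	rs4148413	499	236	43	0.21	0.17
EPHX2	rs4149259	569	212	22	0.16	0.17
DFFB	rs4376673	694	106	1	0.07	0.09
SLC2A1	rs4658	506	266	26	0.20	0.21
ESR2	rs4986938	329	367	103	0.36	0.37
RPTOR	rs61750765	575	208	17	0.15	0.24
SLC22A1	rs628031	302	372	122	0.39	0.40
EPHX2	rs751141	652	137	9	0.10	0.11
CMPK1	rs7543016	240	409	143	0.44	0.45
GSTP1	rs762803	289	402	108	0.39	0.39
CES1	rs76336259	714	87	0	0.05	0.06
BLK	rs922483	429	304	61	0.27	0.23
PPARA	rs9626814	627	163	9	0.11	0.10
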