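cell_line	disease	read_count	fraction_pct	v_gene	d_gene	j_gene	junction_aa
NALM-19	B-ALL	425	36.08	IGHV1-3	IGHD6-6	IGHJ4	CARDRV*QL_PPPLRDYW
MHH-CALL-4	B-ALL	214	14.33	TRAV8-2		TRAJ8	CVVGL_QKLVF
MHH-CALL-4	B-ALL	163	10.92	IGHV2-26	IGHD2-21	IGHJ5	CARIRPRAVR_CGSP*GPDPW
KASUMI-2	B-ALL	3491	60.82	IGLV1-40		IGLJ3	CQSYD_AGVF
MUTZ-5	B-ALL	1632	76.30	IGLV2-34		IGLJ2	CSSYA_HLVVF
REH	B-ALL	100	16.21	IGHV3-15	IGHD3-10	IGHJ6	CTTGMVRGVI_YYYYGMDVW
RS4;11	B-ALL	361	26.05	IGHV6-1	IGHD1-20	IGHJ4	CAREP*LELFDYW
RS4;11	B-ALL	241	17.39	IGHV3-20	IGHD2-8	IGHJ5	CARD*SRY*W_VCYTDWFDPW
RS4;11	B-ALL	173	12.48	IGLV11-55		IGLJ7	CAMG_PQF
RS4;11	B-ALL	36	2.60	IGLV4-3		IGLJ3	CGESHTIDG_SRLRFWVF
NALM-6	B-ALL	15670	74.70	IGLV2-14		IGLJ7	CSSYTSS_ALGAVF
NALM-6	B-ALL	2479	11.82	IGLV4-3		IGLJ3	CGESHTIDGQ_RLQAPGGVF
NALM-6	B-ALL	2229	10.63	IGHV1-69	IGHD3-10	IGHJ6	CARDRRGEWPPSDYYYYYMDVW
KE-37	T-ALL	656	56.21	TRBV3-2	TRBD1	TRBJ1-5	CASSQDSGTG_RVGNQPQHF
ALL-SIL	T-ALL	2364	51.42	TRGV7		TRGJ1	CATWGSG_YYKKLF
ALL-SIL	T-ALL	909	19.77	TRBV18	TRBD1	TRBJ2-1	CASSPMEK_GHKGEQFF
ALL-SIL	T-ALL	482	10.49	TRBV7-9	TRBD1	TRBJ2-7	CASSLDT_WYEQYF
ALL-SIL	T-ALL	221	4.81	TRGV9		TRGJ1	CALWR*_YYKKLF
ALL-SIL	T-ALL	86	1.87	TRDV2		TRDJ1	CACDK_DKLIF
MOLT-3	T-ALL	2913	6.95	TRBV10-3		TRBJ2-5	CAISEPTG_SEETQYF
MOLT-3	T-ALL	231	0.55	TRAV1-1		TRAJ33	CAVRDHPW_SNYQLIW
MOLT-3	T-ALL	97	0.23	TRAV1-1		TRAJ24	CAVKMEQ_WGKLQF
JM1	B cell lymphoma unspecified	10946	48.32	IGLV3-1		IGLJ6	CQAWD_QPNVF
JM1	B cell lymphoma unspecified	7877	34.78	IGLV3-10		IGLJ6	CYSTDSS_VIIANVF
JM1	B cell lymphoma unspecified	1135	5.01	IGLV8-61		IGLJ7	CV_VF
HT	B cell lymphoma unspecified	18074	89.54	IGKV3-11		IGKJ5	CQQRTNWPITF
HT	B cell lymphoma unspecified	1488	7.37	IGHV3-53	IGHD1-1	IGHJ4	CARASFAT_*LYFDSW
BV-173	Blast phase CML/B-ALL	3764	57.83	IGHV3-21	IGHD2-15	IGHJ3	CASQIL*WW*_PYRGAFDIW
BV-173	Blast phase CML/B-ALL	157	11.88	IGKV2-29		IGKJ3	*MQGIH_SSLFTF
BV-173	Blast phase CML/B-ALL	35	2.65	TRAV8-7		TRAJ19	CAGADRLQTGMRGAFDL
Toledo	DLBCL	11815	58.54	IGLV2-14		IGLJ7	CSSYTS_QHSVF
Toledo	DLBCL	6830	33.84	IGLV3-21		IGLJ6	CQVWDSS_*SPNVF
Toledo	DLBCL	316	1.57	IGLV8-61		IGLJ7	CV_VF
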