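# Haplogroup motif table for the Siberian-specific western Eurasian
# subclade analysis.  `motif` lists the variants defining the branch
# relative to its parent (space-separated canonical labels, positions in
# rCRS coordinates).
#
# source = published : diagnostic variants as printed in the study
#                      (e.g. U7a4b = 16150; U2e1i = 16214 16258 2626
#                      5814 13914 14587; U2e2 = 8473; U8a2 = 827 1700;
#                      U5a2a1f = 709; N1a1a1a1a = 16189)
# source = synthetic : placeholder motifs standing in for the unpublished
#                      ancestral-path diagnostics (the full PhyloTree
#                      motifs are not reproduced here); positions are
#                      invented for testing and must not be used to call
#                      real data.
haplogroup	parent	motif	source
mtMRCA			synthetic
R	mtMRCA	73	synthetic
U	R	12308	synthetic
U2	U	16051	synthetic
U2e	U2	3720	synthetic
U2e1	U2e	15907	synthetic
U2e1b	U2e1	4418	synthetic
U2e1b3	U2e1b	10908	synthetic
U2e1i	U2e1	16214 16258 2626 5814 13914 14587	published
U2e2	U2e	8473	published
U3	U	16343	synthetic
U3b	U3	9656	synthetic
U3b1	U3b	4188	synthetic
U3b1c	U3b1	6518	synthetic
U3b2	U3b	13743	synthetic
U3b2c	U3b2	1598	synthetic
U4	U	11332	synthetic
U4b	U4	8818	synthetic
U4b1	U4b	6047	synthetic
U4b1b	U4b1	5567	synthetic
U4b1b1	U4b1b	15693	synthetic
U5	U	3197	synthetic
U5a	U5	14793	synthetic
U5a2	U5a	16256	synthetic
U5a2a	U5a2	13827	synthetic
U5a2a1	U5a2a	16399	synthetic
U5a2a1f	U5a2a1	709	published
U7	U	8684	synthetic
U7a	U7	16309	synthetic
U7a4	U7a	5360	synthetic
U7a4b	U7a4	16150	published
U8	U	3480	synthetic
U8a	U8	282	synthetic
U8a2	U8a	827 1700	published
K	U8	16224 16311	synthetic
K1	K	497	synthetic
K1a	K1	10398	synthetic
K1a3	K1a	10978	synthetic
K1a3b	K1a3	2905	synthetic
K1a17	K1a	16093	synthetic
K1a17b	K1a17	11866	synthetic
K1a32	K1a	6260	synthetic
K1b	K1	5913	synthetic
K1b2	K1b	9716	synthetic
K1b2a	K1b2	14148	synthetic
K1b2a2	K1b2a	606	synthetic
K1b2a2b	K1b2a2	7604	synthetic
K2	K	9962	synthetic
K2a	K2	10550	synthetic
K2a5	K2a	14002	synthetic
K2a5b	K2a5	4561	synthetic
HV	R	14766	synthetic
HV1	HV	16067	synthetic
HV1a	HV1	4388	synthetic
HV1a1	HV1a	8014	synthetic
HV1a1a	HV1a1	6253	synthetic
HV1a1a1	HV1a1a	9336	synthetic
HV1a1a2	HV1a1a	11440	synthetic
H	HV	2706 7028	synthetic
H8	H	13101	synthetic
H8b	H8	5471	synthetic
H8b1	H8b	12634	synthetic
H8b1a	H8b1	14869	synthetic
H8b1b	H8b1	3736	synthetic
H49	H	8838	synthetic
H49c	H49	15148	synthetic
JT	R	4216	synthetic
J	JT	10398 12612	synthetic
J2	J	7476	synthetic
J2a	J2	10499	synthetic
J2a2	J2a	11377	synthetic
J2a2b	J2a2	15257	synthetic
J2a2b3	J2a2b	6671	synthetic
T	JT	4917	synthetic
T2	T	11812	synthetic
T2g	T2	16292	synthetic
T2g1	T2g	13965	synthetic
T2g1a	T2g1	10559	synthetic
T2g1a1	T2g1a	1888	synthetic
N	mtMRCA	8701	synthetic
N1	N	10238	synthetic
N1a	N1	16147	synthetic
N1a1	N1a	10398	synthetic
N1a1a	N1a1	15043	synthetic
N1a1a1	N1a1a	16320	synthetic
N1a1a1a	N1a1a1	199	synthetic
N1a1a1a1	N1a1a1a	12822	synthetic
N1a1a1a1a	N1a1a1a1	16189	published
X	N	6221	synthetic
X2	X	1719	synthetic
X2e	X2	15310	synthetic
X2e2	X2e	225	synthetic
X2e2a	X2e2	8705	synthetic
X2e2a1	X2e2a	13708	synthetic
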