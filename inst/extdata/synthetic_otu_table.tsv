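#OTU ID	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010	S011	S012	S013	S014	S015	S016	taxonomy
OTU_0001	4	7	53	22	13	35	22	5	48	40	40	33	12	74	40	16	k__Bacteria; p__Firmicutes; g__Genus001
OTU_0002	4	6	37	21	3	0	11	5	10	4	11	4	6	82	3	6	k__Bacteria; p__Bacteroidetes; g__Genus002
OTU_0003	4	15	53	29	2	12	29	32	28	20	4	31	3	5	0	0	k__Bacteria; p__Proteobacteria; g__Genus003
OTU_0004	2	5	29	2	2	0	4	0	18	0	2	6	0	6	2	8	k__Bacteria; p__Actinobacteria; g__Genus004
OTU_0005	0	10	9	69	14	29	53	15	12	29	85	95	54	49	14	44	k__Bacteria; p__Tenericutes; g__Genus005
OTU_0006	7	1	11	1	5	5	3	40	13	75	68	9	14	15	38	116	k__Bacteria; p__Firmicutes; g__Genus006
OTU_0007	429	39	194	182	135	138	58	137	69	88	4	6	69	7	5	16	k__Bacteria; p__Bacteroidetes; g__Genus007
OTU_0008	0	5	3	8	1	1	7	2	5	10	15	2	22	0	1	23	k__Bacteria; p__Proteobacteria; g__Genus008
OTU_0009	0	0	0	2	0	0	0	0	1	0	0	0	0	2	0	0	k__Bacteria; p__Actinobacteria; g__Genus009
OTU_0010	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	1	k__Bacteria; p__Tenericutes; g__Genus010
OTU_0011	0	0	0	0	0	0	0	1	0	0	1	0	0	1	0	1	k__Bacteria; p__Firmicutes; g__Genus011
OTU_0012	6	13	11	29	0	4	19	13	19	12	35	2	9	15	11	23	k__Bacteria; p__Bacteroidetes; g__Genus012
OTU_0013	5	83	36	29	10	4	5	27	20	54	6	18	31	88	37	157	k__Bacteria; p__Proteobacteria; g__Genus013
OTU_0014	1	1	2	1	1	0	1	0	2	4	24	0	2	7	0	22	k__Bacteria; p__Actinobacteria; g__Genus014
OTU_0015	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	k__Bacteria; p__Tenericutes; g__Genus015
OTU_0016	0	5	2	0	0	3	7	7	4	0	2	5	3	2	0	7	k__Bacteria; p__Firmicutes; g__Genus016
OTU_0017	1	2	2	2	0	0	0	0	0	2	2	0	0	1	0	5	k__Bacteria; p__Bacteroidetes; g__Genus017
OTU_0018	2	10	4	18	12	21	39	49	10	0	30	8	5	68	22	6	k__Bacteria; p__Proteobacteria; g__Genus018
OTU_0019	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	k__Bacteria; p__Actinobacteria; g__Genus019
OTU_0020	0	0	0	0	0	0	0	0	1	1	0	0	0	0	0	0	k__Bacteria; p__Tenericutes; g__Genus020
OTU_0021	0	16	72	19	9	40	89	122	11	21	79	17	184	79	45	161	k__Bacteria; p__Firmicutes; g__Genus021
OTU_0022	0	41	15	28	3	3	11	43	18	10	7	4	128	4	8	14	k__Bacteria; p__Bacteroidetes; g__Genus022
OTU_0023	17	73	74	14	16	63	24	16	125	63	143	2	68	4	16	64	k__Bacteria; p__Proteobacteria; g__Genus023
OTU_0024	0	3	1	2	1	0	6	2	1	0	4	0	6	3	0	18	k__Bacteria; p__Actinobacteria; g__Genus024
OTU_0025	10	44	28	20	1	10	3	1	6	12	29	3	3	10	12	7	k__Bacteria; p__Tenericutes; g__Genus025
OTU_0026	0	0	0	0	0	0	2	0	0	0	1	0	2	0	0	0	k__Bacteria; p__Firmicutes; g__Genus026
OTU_0027	0	3	20	4	1	11	1	2	7	2	12	0	0	7	1	15	k__Bacteria; p__Bacteroidetes; g__Genus027
OTU_0028	13	40	13	2	11	18	29	20	9	36	8	19	42	52	5	32	k__Bacteria; p__Proteobacteria; g__Genus028
OTU_0029	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	k__Bacteria; p__Actinobacteria; g__Genus029
OTU_0030	16	22	28	142	18	2	15	2	65	5	5	0	1	7	11	17	k__Bacteria; p__Tenericutes; g__Genus030
OTU_0031	0	3	1	1	0	0	1	1	1	0	2	0	0	0	0	1	k__Bacteria; p__Firmicutes; g__Genus031
OTU_0032	1	9	2	3	3	2	1	0	1	2	5	1	10	2	1	2	k__Bacteria; p__Bacteroidetes; g__Genus032
OTU_0033	0	1	1	6	0	0	19	4	3	3	2	3	1	0	1	1	k__Bacteria; p__Proteobacteria; g__Genus033
OTU_0034	29	0	33	95	11	10	18	8	73	60	103	27	21	32	54	44	k__Bacteria; p__Actinobacteria; g__Genus034
OTU_0035	7	1	3	2	1	0	0	2	1	0	2	0	0	1	0	2	k__Bacteria; p__Tenericutes; g__Genus035
OTU_0036	2	6	51	6	1	3	65	36	7	7	16	3	16	0	3	2	k__Bacteria; p__Firmicutes; g__Genus036
OTU_0037	0	2	9	32	2	1	11	0	23	13	7	2	9	1	1	9	k__Bacteria; p__Bacteroidetes; g__Genus037
OTU_0038	0	0	2	1	0	6	1	0	9	2	1	0	0	3	6	2	k__Bacteria; p__Proteobacteria; g__Genus038
OTU_0039	0	7	1	1	0	0	0	4	1	0	3	1	2	0	2	6	k__Bacteria; p__Actinobacteria; g__Genus039
OTU_0040	0	8	11	91	41	0	17	6	36	7	15	43	29	1	24	25	k__Bacteria; p__Tenericutes; g__Genus040
OTUB_001	2	2	0	2	2	0	2	2	0	0	0	0	0	0	0	0	k__Bacteria; p__Firmicutes; g__Genus041
OTUB_002	0	2	2	0	0	0	0	2	2	0	0	0	0	0	0	0	k__Bacteria; p__Bacteroidetes; g__Genus042
OTUB_003	0	2	2	2	0	2	0	2	2	0	0	0	0	0	0	0	k__Bacteria; p__Proteobacteria; g__Genus043
OTUB_004	0	2	0	0	0	2	2	0	2	0	0	0	0	0	0	0	k__Bacteria; p__Actinobacteria; g__Genus044
OTUB_005	0	0	0	0	2	0	2	0	2	0	0	0	0	0	0	0	k__Bacteria; p__Tenericutes; g__Genus045
OTUB_006	2	0	2	0	2	0	0	0	2	0	0	0	0	0	0	0	k__Bacteria; p__Firmicutes; g__Genus046
OTUB_007	2	0	0	0	2	2	0	2	0	0	0	0	0	0	0	0	k__Bacteria; p__Bacteroidetes; g__Genus047
OTUB_008	0	2	0	0	2	0	2	0	0	0	0	0	0	0	0	0	k__Bacteria; p__Proteobacteria; g__Genus048
OTUB_009	2	0	0	2	2	2	0	2	0	0	0	0	0	0	0	0	k__Bacteria; p__Actinobacteria; g__Genus049
OTUB_010	2	2	2	0	0	2	2	2	0	0	0	0	0	0	0	0	k__Bacteria; p__Tenericutes; g__Genus050
OTUB_011	0	0	2	2	0	0	2	2	0	0	0	0	0	0	0	0	k__Bacteria; p__Firmicutes; g__Genus051
OTUB_012	2	0	2	2	2	2	2	0	0	0	0	0	0	0	0	0	k__Bacteria; p__Bacteroidetes; g__Genus052
OTUB_013	2	2	2	2	0	2	2	2	2	0	0	0	0	0	0	0	k__Bacteria; p__Proteobacteria; g__Genus053
OTUB_014	0	2	0	2	0	2	0	0	2	0	0	0	0	0	0	0	k__Bacteria; p__Actinobacteria; g__Genus054
OTUB_015	0	0	0	0	2	0	0	0	2	0	0	0	0	0	0	0	k__Bacteria; p__Tenericutes; g__Genus055
OTUB_016	2	0	2	2	0	0	0	0	0	0	0	0	0	0	0	0	k__Bacteria; p__Firmicutes; g__Genus056
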