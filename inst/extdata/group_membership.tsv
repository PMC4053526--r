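# Allele-to-functional-group membership for KIR3DL1/KIR3DS1.
# tier: high_frequency alleles define the groups; low_frequency alleles were
# assigned by coding-sequence homology/phylogeny to their high-frequency
# homologs. *042 is listed both among the *002-group low-frequency alleles
# and as an unknown (its printed SNP states 202G/607T match no reaction);
# it is carried here with its group listing, while the SNP decision table
# independently returns UNCLASSIFIED for its states.
allele	group	tier
KIR3DL1*004	NULL	high_frequency
KIR3DL1*019	NULL	low_frequency
KIR3DL1*021	NULL	low_frequency
KIR3DL1*036	NULL	low_frequency
KIR3DL1*037	NULL	low_frequency
KIR3DL1*039	NULL	low_frequency
KIR3DL1*040	NULL	low_frequency
KIR3DL1*056	NULL	low_frequency
KIR3DL1*063	NULL	low_frequency
KIR3DL1*072	NULL	low_frequency
KIR3DL1*005	LOW1	high_frequency
KIR3DL1*041	LOW1	low_frequency
KIR3DL1*044	LOW1	low_frequency
KIR3DL1*053	LOW1	low_frequency
KIR3DL1*001	HIGH1	high_frequency
KIR3DL1*016	HIGH1	high_frequency
KIR3DL1*026	HIGH1	low_frequency
KIR3DL1*027	HIGH1	low_frequency
KIR3DL1*043	HIGH1	low_frequency
KIR3DL1*052	HIGH1	low_frequency
KIR3DL1*059	HIGH1	low_frequency
KIR3DL1*060	HIGH1	low_frequency
KIR3DL1*061	HIGH1	low_frequency
KIR3DL1*064	HIGH1	low_frequency
KIR3DL1*065	HIGH1	low_frequency
KIR3DL1*067	HIGH1	low_frequency
KIR3DL1*075	HIGH1	low_frequency
KIR3DL1*002	HIGH2	high_frequency
KIR3DL1*015	HIGH2	high_frequency
KIR3DL1*008	HIGH2	high_frequency
KIR3DL1*009	HIGH2	high_frequency
KIR3DL1*020	HIGH2	high_frequency
KIR3DL1*006	HIGH2	low_frequency
KIR3DL1*017	HIGH2	low_frequency
KIR3DL1*018	HIGH2	low_frequency
KIR3DL1*022	HIGH2	low_frequency
KIR3DL1*023	HIGH2	low_frequency
KIR3DL1*024N	HIGH2	low_frequency
KIR3DL1*025	HIGH2	low_frequency
KIR3DL1*028	HIGH2	low_frequency
KIR3DL1*029	HIGH2	low_frequency
KIR3DL1*030	HIGH2	low_frequency
KIR3DL1*031	HIGH2	low_frequency
KIR3DL1*034	HIGH2	low_frequency
KIR3DL1*035	HIGH2	low_frequency
KIR3DL1*038	HIGH2	low_frequency
KIR3DL1*042	HIGH2	low_frequency
KIR3DL1*051	HIGH2	low_frequency
KIR3DL1*054	HIGH2	low_frequency
KIR3DL1*057	HIGH2	low_frequency
KIR3DL1*062	HIGH2	low_frequency
KIR3DL1*066	HIGH2	low_frequency
KIR3DL1*074	HIGH2	low_frequency
KIR3DL1*076	HIGH2	low_frequency
KIR3DL1*077	HIGH2	low_frequency
KIR3DL1*007	LOW2	high_frequency
KIR3DL1*032	LOW2	low_frequency
KIR3DL1*033	LOW2	low_frequency
KIR3DL1*068	LOW2	low_frequency
KIR3DS1*013	S1	high_frequency
KIR3DS1*010	S1	low_frequency
KIR3DS1*011	S1	low_frequency
KIR3DS1*012	S1	low_frequency
KIR3DS1*014	S1	low_frequency
KIR3DS1*045	S1	low_frequency
KIR3DS1*046	S1	low_frequency
KIR3DS1*047	S1	low_frequency
KIR3DS1*048	S1	low_frequency
KIR3DS1*049N	S1	low_frequency
KIR3DS1*050	S1	low_frequency
KIR3DS1*055	S1	low_frequency
KIR3DS1*058	S1	low_frequency
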