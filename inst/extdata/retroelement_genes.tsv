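# Survey of orthologous retroelement (Metaviridae gag/integrase and ERV env)
# derived domesticated genes with de novo gained introns (27 genes, of 34
# analyzed; the 7 intronless genes, e.g. RTL1 and LDOC1, are not listed).
# Retroelement-derived genes are whole-TE domestications; the single fusion
# exception (SCAND3) is flagged for exclusion from eligibility. location uses
# UTR5/CDS for introns in both regions and A|B where the source is ambiguous
# ("5' UTR or coding", "5' UTR or 3' UTR").
gene	te_group	progenitor_class	origin_route	exclusion_flag	introns_min	introns_max	location
RGAG1	gag_MART	retroelement	whole_TE	FALSE	3	3	UTR5/CDS
ZCCHC16	gag_MART	retroelement	whole_TE	FALSE	2	6	UTR5
ZCCHC5	gag_MART	retroelement	whole_TE	FALSE	1	1	UTR5
PEG10	gag_MART	retroelement	whole_TE	FALSE	1	2	UTR5|CDS
LDOC1L	gag_MART	retroelement	whole_TE	FALSE	1	1	UTR5
RGAG4	gag_MART	retroelement	whole_TE	FALSE	1	1	UTR3
C22ORF29	gag_MART	retroelement	whole_TE	FALSE	2	2	UTR5
FAM127B	gag_MART	retroelement	whole_TE	FALSE	1	1	CDS
PNMA2	gag_PNMA	retroelement	whole_TE	FALSE	2	2	UTR5
PNMA3	gag_PNMA	retroelement	whole_TE	FALSE	1	1	UTR5
MOAP1	gag_PNMA	retroelement	whole_TE	FALSE	1	2	UTR5
PNMA5	gag_PNMA	retroelement	whole_TE	FALSE	3	3	UTR5|UTR3
PNMA6A	gag_PNMA	retroelement	whole_TE	FALSE	1	2	UTR5|CDS
PNMA6B	gag_PNMA	retroelement	whole_TE	FALSE	1	1	UTR5
ZCCHC12	gag_PNMA	retroelement	whole_TE	FALSE	3	3	UTR5
ZCCHC18	gag_PNMA	retroelement	whole_TE	FALSE	2	2	UTR5
CCDC8	gag_PNMA	retroelement	whole_TE	FALSE	1	1	CDS
PNMAL1	gag_PNMA	retroelement	whole_TE	FALSE	2	2	UTR5
PNMAL2	gag_PNMA	retroelement	whole_TE	FALSE	1	1	CDS
ARC	gag_ARC	retroelement	whole_TE	FALSE	2	2	UTR3
GIN1	rve	retroelement	whole_TE	FALSE	7	7	UTR5/CDS
SCAND3	rve	retroelement	whole_TE	TRUE	3	3	CDS
KRBA2	rve	retroelement	whole_TE	FALSE	1	3	UTR5|CDS
NYNRIN	rve	retroelement	whole_TE	FALSE	8	8	UTR5/CDS
ERVFRD-1	env_ERV	retroelement	whole_TE	FALSE	1	1	UTR5
ERVW-1	env_ERV	retroelement	whole_TE	FALSE	1	1	UTR5
SYNCYTIN_B	env_ERV	retroelement	whole_TE	FALSE	2	2	UTR5
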