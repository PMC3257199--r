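# Transcribed origin-timing table: LCA node at which each intron-containing
# domesticated gene family originated on the chordate species tree
# (species_tree.nwk carries the same node names). Genes from the survey
# tables that the timing table omits (e.g. JRK, SETMAR, RAG1, GIN1, the env
# genes) are treated as origin "unplaced" and excluded from numeric tallies.
gene	progenitor_class	origin_node
RGAG1	retroelement	Eutheria
ZCCHC16	retroelement	Eutheria
ZCCHC5	retroelement	Eutheria
PEG10	retroelement	Theria
LDOC1L	retroelement	Eutheria
RGAG4	retroelement	Eutheria
C22ORF29	retroelement	Eutheria
PNMA2	retroelement	Eutheria
PNMA3	retroelement	Eutheria
MOAP1	retroelement	Eutheria
PNMA5	retroelement	Eutheria
PNMA6A	retroelement	Eutheria
PNMA6B	retroelement	Eutheria
ZCCHC12	retroelement	Eutheria
ZCCHC18	retroelement	Eutheria
CCDC8	retroelement	Eutheria
PNMAL1	retroelement	Eutheria
PNMAL2	retroelement	Eutheria
ARC	retroelement	Tetrapoda
SCAND3	retroelement	Theria
KRBA2	retroelement	Eutheria
NYNRIN	retroelement	Theria
POGK	DNA_transposon	Amniota
ZBED1	DNA_transposon	Tetrapoda
ZNF862	DNA_transposon	Theria
Buster3	DNA_transposon	Eutheria
PRKRIR	DNA_transposon	Gnathostomata
THAP9	DNA_transposon	Gnathostomata
HARBI1	DNA_transposon	Gnathostomata
NAIF1	DNA_transposon	Gnathostomata
PGBD1	DNA_transposon	Eutheria
PGBD2	DNA_transposon	Theria
PGBD5	DNA_transposon	Chordata
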