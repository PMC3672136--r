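description	accession	experiments_observed	sum_count	synthetic
CCT5 T-complex protein 1 subunit epsilon (TCP1)	IPI00575509	3	14	FALSE
ANXA6 Annexin A6	IPI00576535	3	14	FALSE
LOC429161 similar to otolin-1	IPI00591329	3	12	FALSE
PPP2R1B Protein phosphatase 2, regulatory subunit A, beta	IPI00811766	3	8	FALSE
ALAD Delta-aminolevulinic acid dehydratase	IPI00600895	3	5	FALSE
LOC395261 Filamin	IPI00591901	2	21	FALSE
DDOST Dolichyl-diphosphooligosaccharide-protein glycosyltransferase	IPI00602654	2	19	FALSE
CKAP4 Cytoskeleton-associated protein 4	IPI00584755	2	13	FALSE
PSMD13 26S proteasome non-ATPase regulatory subunit 13	IPI00601716	2	12	FALSE
IMMT Mitochondrial inner membrane protein	IPI00595381	2	7	FALSE
ACAD9 Acyl-CoA dehydrogenase family member 9	IPI00821733	2	6	FALSE
SDHA Succinate dehydrogenase	IPI00682371	2	6	FALSE
EIF3E Eukaryotic translation initiation factor 3 subunit E	IPI00593255	2	6	FALSE
RCJMB04_9j22 RNA binding motif protein, X-linked	IPI00575141	2	6	FALSE
SMC1 Structural maintenance of chromosomes protein 1A	IPI00601137	2	5	FALSE
USP5 Ubiquitin carboxyl-terminal hydrolase 5	IPI00579016	2	5	FALSE
LRPAP1 Low density lipoprotein receptor-related protein associated protein 1	IPI00588285	2	5	FALSE
13 kDa protein Desru_0254	IPI00818044	2	5	FALSE
SEPT2 Septin-2	IPI00584652	2	5	FALSE
ATP2A2 Sarcoplasmic/endoplasmic reticulum calcium ATPase 2 (SERCA2)	IPI00590859	2	4	FALSE
ARHGDIB similar to D4-GDP-dissociation inhibitor	IPI00588997	2	4	FALSE
RRBP1 Ribosome-binding protein 1	IPI00573911	2	4	FALSE
CSE1L similar to cellular apoptosis susceptibility protein	IPI00582808	2	4	FALSE
TMC6 Transmembrane channel-like protein 6	IPI00679585	2	3	FALSE
96 kDa protein Solute carrier family 12 member 2 (NKCC1)	IPI00600831	2	3	FALSE
CKM Creatine kinase M-type	IPI00592568	2	3	FALSE
AKT1 Serine/threonine protein kinase	IPI00582661	2	3	FALSE
TF Ovotransferrin	IPI00683271	1	17	FALSE
HADH similar to L-3-hydroxyacyl-Coenzyme A dehydrogenase	IPI00682714	1	11	FALSE
PSMD6 26S proteasome non-ATPase regulatory subunit 6	IPI00601017	1	11	FALSE
LOC395260 Chicken gizzard actin-binding protein260	IPI00593882	1	10	FALSE
792 kDa protein Nesprin 2	IPI00585154	1	9	FALSE
COL8A2 Collagen, type VIII, alpha 2	IPI00584704	1	8	FALSE
PRPS1 Ribose-phosphate pyrophosphokinase 1	IPI00599017	1	8	FALSE
SEC61A1 similar to sec61-like protein	IPI00594100	1	7	FALSE
SERPINB14B Ovalbumin-related protein Y	IPI00573738	1	7	FALSE
ACTR3 Actin-related protein 3	IPI00587398	1	7	FALSE
P4HA1 similar to Prolyl 4-hydroxylase alpha-1 subunit	IPI00598417	1	7	FALSE
CSNK2A1 Casein kinase II subunit alpha	IPI00584282	1	7	FALSE
TACSTD1 Epithelial cell adhesion molecule	IPI00589818	1	7	FALSE
PSMD5 26S proteasome non-ATPase regulatory subunit 5	IPI00582424	1	7	FALSE
NANS Sialic acid synthase	IPI00573236	1	6	FALSE
DNAJB11 DnaJ (Hsp40) homolog, subfamily B	IPI00571322	1	6	FALSE
PPP1R7 Protein phosphatase 1 regulatory subunit 7	IPI00574127	1	5	FALSE
LOC429867 Plectin-1	IPI00587768	1	5	FALSE
WDR61 WD repeat-containing protein 61	IPI00584957	1	5	FALSE
GNAI1 Guanine nucleotide-binding protein G(i) subunit alpha-1	IPI00585976	1	5	FALSE
LOC396473 Myristoylated alanine-rich C-kinase substrate	IPI00591767	1	5	FALSE
GOLPH3 similar to trans-Golgi protein GMx33	IPI00603208	1	5	FALSE
RCJMB04_9n20 Isocitrate dehydrogenase [NAD] subunit beta	IPI00604247	1	5	FALSE
PSMD2 26S Proteasome non-ATPase regulatory subunit 2	IPI00592623	1	4	FALSE
TTC38 Tetratricopeptide repeat protein 38	IPI00589671	1	4	FALSE
PRKAR1A cAMP-dependent protein kinase type I-alpha regulatory subunit	IPI00573783	1	4	FALSE
CRMP1 Collapsin response mediator protein-1A	IPI00579627	1	4	FALSE
MOSC2 similar to MOCO sulphurase C-terminal domain containing 2	IPI00591218	1	4	FALSE
GNAI2 Guanine nucleotide-binding protein G(i) subunit alpha-2	IPI00589157	1	4	FALSE
RCJMB04_1g23 Cytoplasmic dynein 1 light intermediate chain 2	IPI00585015	1	4	FALSE
RCJMB04_7k22 Septin9	IPI00592494	1	4	FALSE
NCSTN Nicastrin	IPI00572509	1	3	FALSE
PDHA1 Pyruvate dehydrogenase E1	IPI00595745	1	3	FALSE
RCJMB04_1d17 Regulation of nuclear pre-mRNA domain-containing protein 1B	IPI00651204	1	3	FALSE
ANP32A Acidic leucine-rich nuclear phosphoprotein 32 family member A	IPI00589812	1	3	FALSE
ADD1 Alpha-adducin	IPI00602199	1	3	FALSE
MAN2B2 similar to mannosidase, alpha, class 2B, member 2	IPI00572503	1	3	FALSE
GNA11 Guanine nucleotide-binding protein G11 alpha-subunit	IPI00577333	1	3	FALSE
EIF2S1 Eukaryotic translation initiation factor 2 subunit 1	IPI00590033	1	3	FALSE
POFUT1 GDP-fucose protein O-fucosyltransferase 1	IPI00592268	1	3	FALSE
UGP2 UTP—glucose-1-phosphate uridylyltransferase	IPI00601449	1	3	FALSE
EEA1 Early endosome antigen 1	IPI00571138	1	3	FALSE
BZW2 Basic leucine zipper and W2 domain-containing protein 2	IPI00577749	1	3	FALSE
ATP1B3 Sodium/potassium-transporting ATPase subunit beta-3	IPI00580874	1	3	FALSE
STAG2 similar to stromal antigen 2	IPI00599733	1	3	FALSE
RCJMB04_12m17 Short/branched chain specific acyl-CoA dehydrogenase	IPI00602866	1	3	FALSE
PSMC1 26S protease regulatory subunit 4	IPI00821206	1	3	FALSE
PITPNB Phosphatidylinositol transfer protein, beta	IPI00581857	1	3	FALSE
HHATL Hedgehog acyltransferase-like	IPI00599649	1	3	FALSE
RCJMB04_1m9 Thyroid hormone receptor associated protein 3	IPI00583448	1	2	FALSE
ATP13A3 similar to type V P-type ATPase	IPI00593562	1	2	FALSE
COL18A1 collagen, type XVIII, alpha 1	IPI00596507	1	2	FALSE
PCYOX1 Prenylcysteine oxidase 1 precursor	IPI00573599	1	2	FALSE
TALDO1 Transaldolase	IPI00571239	1	2	FALSE
PA2G4 similar to proliferation-associated protein 1, partial	IPI00597630	1	2	FALSE
FDPS Farnesyl pyrophosphate synthase	IPI00584175	1	2	FALSE
PSMD11 26S proteasome subunit p44.5	IPI00598610	1	2	FALSE
TXNDC10 Protein disulfide-isomerase TMX3	IPI00574033	1	2	FALSE
C14orf149 Proline racemase-like	IPI00574864	1	2	FALSE
ERGIC1 Endoplasmic reticulum-golgi intermediate compartment (ERGIC) 1	IPI00575314	1	2	FALSE
COPS4 COP9 signalosome complex subunit 4	IPI00578250	1	2	FALSE
SCLY Selenocysteine lyase	IPI00585168	1	2	FALSE
RPL27A Ribosomal protein L27a	IPI00587714	1	2	FALSE
C12orf10 Chromosome 12 open reading frame 10	IPI00588179	1	2	FALSE
NUMA1 Nuclear mitotic apparatus protein 1	IPI00590550	1	2	FALSE
VAT1 similar to Vesicle amine transport protein 1 homolog	IPI00591027	1	2	FALSE
CNOT1 similar to CCR4-NOT transcription complex, subunit 1	IPI00596498	1	2	FALSE
CARKD Carbohydrate kinase domain containing	IPI00596628	1	2	FALSE
PAFAH1B1 Platelet-activating factor acetylhydrolase IB subunit alpha	IPI00596826	1	2	FALSE
SEC23B Protein transport protein Sec23A	IPI00601344	1	2	FALSE
RPL4 Ribosomal protein L4	IPI00575596	1	2	FALSE
FARSA Phenylalanyl-tRNA synthetase alpha chain	IPI00584214	1	2	FALSE
HDGF similar to hepatoma-derived growth factor	IPI00812721	1	2	FALSE
CENPT Centromere protein T	IPI00586160	1	2	FALSE
SPARC Osteonectin	IPI00575874	1	2	FALSE
synthetic placeholder for one unrecoverable table row	SYNTHETIC_NSC_ONLY_1	1	2	TRUE
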