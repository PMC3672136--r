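description	accession	experiments_observed	sum_count	synthetic
MYO7A similar to Myosin VIIA	IPI00576099	3	21	FALSE
GSTO1 similar to glutathione-S-transferase homolog isoform 2	IPI00593631	3	15	FALSE
PSMA1 Proteasome subunit alpha type-1	IPI00820937	3	8	FALSE
TLR3 Toll-like receptor 3	IPI00590386	3	7	FALSE
ACOT7 similar to acyl-CoA hydrolase	IPI00571165	3	6	FALSE
STARD10 StAR-related lipid transfer (START) domain	IPI00579939	3	6	FALSE
SCAMP1 similar to secretory carrier membrane protein 1	IPI00589108	3	6	FALSE
CRABP1 Cellular retinoic acid-binding protein 1	IPI00602403	2	13	FALSE
PGM2L1 Phosphoglucomutase 2-like 1	IPI00594777	2	13	FALSE
PSMB1 Proteasome subunit beta type-1	IPI00583929	2	11	FALSE
RAB7A similar to RAB7 protein	IPI00601244	2	10	FALSE
RCJMB04_3m23 Vesicle-associated membrane protein-associated protein A	IPI00819526	2	9	FALSE
RAB2A Ras-related protein Rab-2A	IPI00582079	2	7	FALSE
OSBPL1A similar to oxysterol-binding protein-like 1A isoform 2	IPI00582014	2	7	FALSE
PSMB2 Proteasome subunit beta type-2	IPI00588689	2	7	FALSE
RCJMB04_32c11 Elongation factor 1-beta	IPI00597497	2	7	FALSE
LOC776238 similar to rabconnectin	IPI00599229	2	6	FALSE
Eukaryotic translation initiation factor 5A-1	IPI00577746	2	6	FALSE
NDUFV2 similar to NADH dehydrogenase [ubiquinone] flavoprotein 2	IPI00571196	2	6	FALSE
LPGAT1 Lysophosphatidylglycerol acyltransferase 1	IPI00587613	2	6	FALSE
NDUFS3 NADH dehydrogenase [ubiquinone] Fe-S protein 3 precursor	IPI00572839	2	6	FALSE
SNRPB Small nuclear ribonucleoprotein-associated protein B'	IPI00603436	2	5	FALSE
COX7A2L similar to cytochrome c oxidase polypeptide VIIa-heart	IPI00579138	2	5	FALSE
ATP5H ATP synthase subunit d	IPI00594088	2	4	FALSE
COX4I1 Cytochrome c oxidase subunit IV	IPI00576496	2	4	FALSE
NDUFB4 NADH dehydrogenase [ubiquinone] 1 beta subcomplex subunit 4	IPI00812364	2	4	FALSE
SLC1A6 similar to neuronal glutamate transporter EAAT4	IPI00594618	2	4	FALSE
LRP8 Low-density lipoprotein receptor-related protein 8	IPI00581287	2	4	FALSE
ABHD10 Abhydrolase domain containing 10	IPI00602566	2	4	FALSE
RPL24 similar to Ribosomal protein L24	IPI00586190	2	3	FALSE
ATP1B1 Sodium/potassium-transporting ATPase subunit beta-1	IPI00579860	2	3	FALSE
EFCAB6 EF-hand calcium binding domain 6	IPI00596390	2	3	FALSE
SNRPA1 U2 small nuclear ribonucleoprotein A	IPI00575703	2	3	FALSE
TOLLIP Toll-interacting protein	IPI00590435	2	3	FALSE
LOC770724 NADH dehydrogenase [ubiquinone] 1 beta subcomplex subunit 6	IPI00602158	2	3	FALSE
HIP1 Huntingtin-interacting protein 1	IPI00818913	1	5	FALSE
SLC17A8 similar to vesicular glutamate transporter 3	IPI00579531	1	4	FALSE
20 kDa protein Mesencephalic astrocyte-derived neurotrophic factor precursor	IPI00602683	1	4	FALSE
ARL1 ADP-ribosylation factor-like 1	IPI00578232	1	3	FALSE
NDUFS4 similar to NADH dehydrogenase	IPI00597417	1	3	FALSE
TARDBP TAR DNA-binding protein 43	IPI00596633	1	3	FALSE
64 kDa protein Synapsin-3	IPI00578493	1	3	FALSE
TMEM35 Transmembrane protein 35	IPI00571302	1	3	FALSE
APBA1 similar to adaptor protein X11alpha	IPI00580720	1	3	FALSE
RCJMB04_1g4 Serine/arginine-rich splicing factor 10 isoform 2	IPI00584494	1	3	FALSE
HSPH1 Heat shock protein 105 kDa	IPI00590633	1	3	FALSE
USP7 Ubiquitin specific peptidase 7	IPI00580665	1	3	FALSE
ITPA Inosine triphosphate pyrophosphatase	IPI00594943	1	2	FALSE
MYL1 Myosin light chain 1, skeletal muscle isoform	IPI00578052	1	2	FALSE
KIF21A Kinesin family member 21A	IPI00588407	1	2	FALSE
APOA1BP Apolipoprotein A-I binding protein	IPI00576049	1	2	FALSE
ATP5I ATP synthase, H+ transporting	IPI00576667	1	2	FALSE
RBBP4 Histone-binding protein RBBP4	IPI00592914	1	2	FALSE
ATP6V1H similar to 54 kDa vacuolar H(+)-ATPase subunit	IPI00593252	1	2	FALSE
ACSL4 similar to Acyl-CoA synthetase	IPI00593747	1	2	FALSE
BRWD2 Bromodomain and WD repeat-containing protein 2	IPI00594946	1	2	FALSE
YKT6 Synaptobrevin homolog YKT6	IPI00597412	1	2	FALSE
AIFM1 Apoptosis-inducing factor 1, mitochondrial	IPI00601063	1	2	FALSE
RPL9 60S ribosomal protein L9	IPI00601775	1	2	FALSE
STARD8 StAR-related lipid transfer (START) domain containing 8	IPI00812461	1	2	FALSE
ACP1 Low molecular weight phosphotyrosine protein phosphatase	IPI00578195	1	2	FALSE
USO1 General vesicular transport factor p115	IPI00578084	1	2	FALSE
INPP5F Phosphatidylinositide phosphatase SAC2	IPI00577046	1		FALSE
synthetic placeholder for one unrecoverable table row	SYNTHETIC_HC_ONLY_1	1	2	TRUE
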