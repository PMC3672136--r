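description	accession	experiments_observed	count_HC	count_NSC	p_value
SCCPDH Saccharopine dehydrogenase (putative)	IPI00580273	4	1	34	8.9E-09
RCJMB04_2a4 ATP-dependent RNA helicase DDX3X	IPI00579247	4	1	14	0.0011
TLN1 Talin-1	IPI00586709	5	3	39	0.000000029
SEC31A Protein transport protein Sec31A	IPI00571140	2	1	12	0.0035
SMC3 Structural maintenance of chromosomes protein 3	IPI00598955	3	1	12	0.0035
TXNDC4 similar to Thioredoxin domain containing 4	IPI00679931	2	1	11	0.0061
PARP1 Poly (ADP-ribose) polymerase 1	IPI00588387	3	1	11	0.0061
COL14A1 Collagen alpha-1(XIV) chain	IPI00601719	2	1	10	0.011
SERPINB6 Serpin B6	IPI00572003	4	1	10	0.011
DCPS Decapping enzyme, scavenger	IPI00583720	2	1	10	0.011
AKR1B10 Aldo-keto reductase family 1 member B10	IPI00591510	3	2	19	0.00034
AKR1A1 Alcohol dehydrogenase [NADP+]	IPI00820020	3	1	9	0.018
ACTR2 Actin-related protein 2	IPI00585509	3	1	9	0.018
HDLBP Vigilin	IPI00820163	2	3	26	0.000034
DST Dystonin	IPI00573263	5	2	16	0.0016
GSN Gelsolin	IPI00582056	4	2	16	0.0016
PGM1 Phosphoglucomutase 1	IPI00735086	3	1	8	0.031
AHCY similar to S-adenosylhomocysteine hydrolase	IPI00600960	4	1	8	0.031
PRPSAP2 Phosphoribosyl pyrophosphate synthase-associated protein 2	IPI00590654	3	1	8	0.031
KPNB1 Importin subunit beta-1	IPI00603965	4	1	8	0.031
RCJMB04_7e11 Isocitrate dehydrogenase 2	IPI00577774	5	4	29	0.000028
MYH9 Myosin-9	IPI00572165	6	9	65	2.4E-10
VCL Vinculin	IPI00589062	5	8	56	6.1E-09
ACTN4 Alpha-actinin-4	IPI00572461	6	4	25	0.0002
PGD 6-phosphogluconate dehydrogenase, decarboxylating	IPI00570964	3	2	11	0.02
PDHB similar to Pyruvate dehydrogenase (lipoamide) beta	IPI00601873	3	2	11	0.02
IDH1 similar to cytosolic NADP-dependent isocitrate dehydrogenase	IPI00598809	5	9	49	0.00000059
AKR1B1 Aldose reductase	IPI00591295	3	4	19	0.0035
NCL Nucleolin	IPI00680028	5	3	14	0.013
SEPHS1 Selenophosphate synthetase 1	IPI00576653	2	3	14	0.013
HSPD1 HSP60	IPI00577421	5	9	40	0.000035
HSP90AB1 Heat shock protein HSP 90-beta	IPI00820593	4	11	47	0.037
SERPINH1 Serpin H1	IPI00600018	4	13	53	0.0000047
EEF2 Elongation factor 2	IPI00585747	6	17	69	0.00000019
ANXA8L1 Annexin VIII	IPI00585409	4	4	16	0.013
HBG1;HBG2 Hemoglobin subunit beta	IPI00590350	4	3	11	0.05
CANX Calnexin	IPI00603318	5	3	11	0.05
Histone H1.03	IPI00571411	5	6	21	0.008
CTNNA1 Catenin alpha-1	IPI00600729	5	4	14	0.03
IQGAP1 RasGAP-like with IQ motif	IPI00571767	4	8	26	0.0048
PDIA6 Protein disulfide-isomerase A6 precursor	IPI00586516	5	10	31	0.0029
ALDH1A3 Retinaldehyde dehydrogenase 3	IPI00684362	5	6	18	0.025
GNB2L1 Guanine nucleotide-binding protein subunit beta-2-like 1	IPI00596315	5	5	15	0.041
ATP1A1 ATPase, Na+/K+ transporting, alpha 1 polypeptide	IPI00588683	5	26	71	0.000048
ANXA5 Annexin A5	IPI00592470	6	42	114	0.00000033
GOT1 Aspartate aminotransferase, cytoplasmic	IPI00589564	4	7	19	0.033
EIF4A2 Eukaryotic initiation factor 4A-II	IPI00588868	6	18	47	0.0014
PDIA4 Protein disulfide-isomerase A4 precursor	IPI00589958	4	17	44	0.0021
HSP90B1 Endoplasmin	IPI00570770	6	49	126	0.00000032
TCP1 T-complex protein 1 subunit alpha	IPI00584300	4	7	18	0.046
ACAT1 Acetyl-CoA acetyltransferase 1	IPI00579109	5	9	23	0.026
P4HB Protein disulfide-isomerase	IPI00596673	5	19	48	0.0017
IPO5 similar to Ran_GTP binding protein 5	IPI00572635	3	8	20	0.04
COPA Coatomer subunit alpha	IPI00577325	5	12	29	0.018
ACO2 Aconitase 2	IPI00576187	5	15	33	0.022
FLNB Filamin B	IPI00578831	5	78	170	0.00000073
MYH10 Nonmuscle myosin 10	IPI00576130	5	41	79	0.0037
FLNB Filamin	IPI00576318	3	66	127	0.00027
HSPA5 78 kDa glucose-regulated protein precursor	IPI00590375	6	76	140	0.00041
H4-VII Histone H4	IPI00572919	5	33	58	0.029
MDH2 similar to Malate dehydrogenase 2, NAD	IPI00577857	6	39	68	0.021
TPRXL Putative protein TPRXL	IPI00820086	4	87	147	0.0021
EEF1A1 Elongation factor 1-alpha 1	IPI00589985	6	67	108	0.016
VYGIII Vitellognin 3	IPI00818934	5	84	132	0.013
SERPINB14 Ovalbumin	IPI00583974	4	148	230	0.0019
GAPDH Glyceraldehyde-3-phosphate dehydrogenase	IPI00594653	6	123	188	0.0068
RCJMB04_1h13 Actin, cytoplasmic type 5	IPI00572084	6	225	309	0.02
TUBB2C Tubulin beta-3 chain	IPI00580626	5	155	167	0.00054
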