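description	accession	experiments_observed	count_HC	count_NSC	p_value
OTOF similar to brain otoferlin	IPI00599487	5	321	17	0
AK1 Adenylate kinase isoenzyme 1	IPI00571711	4	17	1	0.000023
ATP6V1B2 V-type proton ATPase subunit B, brain isoform	IPI00584789	3	14	1	0.00019
THOC4 THO complex 4	IPI00576073	4	13	1	0.00039
RPL10A 60S ribosomal protein L10a	IPI00596886	3	12	1	0.00078
CALB2 Calretinin	IPI00598353	5	107	9	7.9E-26
RPS10 Ribosomal protein S10	IPI00584482	3	11	1	0.0016
OCM2 Parvalbumin	IPI00602026	5	30	3	0.0000001
ATP6V1E1 ATPase, H+ transporting, lysosomal 31kDa, V1 subunit E1	IPI00583177	4	10	1	0.0031
FKBP3 FK506 binding protein 3	IPI00588963	4	10	1	0.0031
RAB14 Ras-related protein Rab-14	IPI00582881	3	9	1	0.006
ARL6IP5 ADP-ribosylation-like factor 6 interacting protein 5	IPI00597483	3	9	1	0.006
PEBP1 similar to Phosphatidylethanolamine-binding protein 1	IPI00603045	4	16	2	0.00024
SNAP91 Clathrin coat assembly protein AP180	IPI00595127	3	8	1	0.012
HSD17B10 Hydroxysteroid (17-beta) dehydrogenase 10	IPI00598537	4	8	1	0.012
ATP5F1 ATP synthase B chain	IPI00570686	4	22	3	0.00002
UCHL1 Ubiquitin carboxyl-terminal hydrolase isozyme L1	IPI00595105	3	7	1	0.023
DCI similar to Dodecenoyl-Coenzyme A delta isomerase	IPI00591896	4	7	1	0.023
MYO6 Isoform 1 of Myosin-VI	IPI00572880	5	150	22	4.9E-29
YWHAB 14-3-3 protein beta/alpha	IPI00591852	4	33	5	0.00000028
317 kDa protein Lipopolysaccharide-responsive and beige-like anchor protein isoform 2	IPI00580943	4	19	3	0.00013
ATP6V0A1 V-type proton ATPase	IPI00818110	4	6	1	0.043
ALDH2 Aldehyde dehydrogenase 2 family (mitochondrial)	IPI00589575	4	28	5	0.0000062
RCJMB04_15c3 Vesicle-trafficking protein SEC22b	IPI00583615	4	11	2	0.0058
MAP1B Microtubule-associated protein 1B	IPI00823023	4	41	8	0.000000089
ATP5O ATP synthase	IPI00813389	3	9	2	0.019
ME1 Malic enzyme	IPI00577117	3	9	2	0.019
HSPA4L Heat shock 70kDa protein 4-like	IPI00573597	3	9	2	0.019
RAB11B	IPI00573563	3	9	2	0.019
INPP5K Inositol polyphosphate 5-phosphatase K	IPI00601849	3	9	2	0.019
RAB1A	IPI00684373	5	26	6	0.000062
CBR1 20-hydroxysteroid dehydrogenase	IPI00577014	4	8	2	0.035
SOD1 Superoxide dismutase [Cu-Zn]	IPI00598533	3	8	2	0.035
RCJMB04_24f23 Endoplasmic reticulum resident protein 29	IPI00597655	5	11	3	0.016
ATP6V1A ATPase, H+ transporting, lysosomal 70kDa, V1 subunit A	IPI00579550	4	10	3	0.027
ARF1 ADP-ribosylation factor 1	IPI00822785	4	56	18	0.00000033
RCJMB04_1d23 Rho GDP dissociation inhibitor (GDI) alpha	IPI00585707	5	18	6	0.0045
CLTCL1 similar to Clathrin, heavy polypeptide	IPI00683666	4	112	41	9.3E-10
SLC25A3 Solute carrier family 25 member 3	IPI00573447	5	12	5	0.041
CLTC clathrin heavy chain 1	IPI00829409	6	295	124	2.6E-23
PHB Prohibitin	IPI00574627	4	20	9	0.013
ACLY ATP citrate lyase	IPI00575808	4	33	15	0.0016
SLC25A6 ADP/ATP translocase 3	IPI00600989	6	33	18	0.007
CKB Isoform Bb-CK-2 of Creatine kinase B-type	IPI00604016	6	236	131	5E-12
RCJMB04_11l21 14-3-3 protein zeta	IPI00578632	6	45	27	0.0048
GSTA3 Glutathione S-transferase	IPI00596765	5	25	15	0.032
TPI1 Triosephosphate isomerase	IPI00582452	6	41	26	0.012
LOC429558 similar to histone H2B	IPI00600992	6	51	34	0.009
PPIA Peptidyl-prolyl cis-trans isomerase	IPI00953851	6	37	26	0.036
YWHAQ 14-3-3 protein theta	IPI00577739	6	34	24	0.044
TUBB3 Tubulin beta-4 chain	IPI00603718	4	120	93	0.00058
DYNC1H1 similar to dynein, cytoplasmic, heavy polypeptide 1	IPI00575860	5	153	127	0.0041
TUBA1C Tubulin alpha-1 chain (Fragment)	IPI00575989	6	167	152	0.022
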