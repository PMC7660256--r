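# PdhR binding-site catalogue: 35 gSELEX-chip peaks on the E. coli K-12 genome.
# Transcribed from the published table. Interpretation notes:
#  - The published intensity columns are headed "Intensity (PdhR+pyruvate)" then
#    "Intensity (PdhR alone)", but the text states that peak intensities decreased
#    markedly in the presence of pyruvate and the first column is consistently the
#    larger (e.g. 9889 vs 9234; 3469 vs 383). The first printed column is therefore
#    stored as intensity_no_effector and the second as intensity_effector; this is
#    the only reading consistent with the profile figure and the text.
#  - host_gene is the ORF containing a type-D site (the published "PdhR site" column);
#    '-' for intergenic (type-A/B) sites.
#  - left_dir / right_dir are the printed transcription-direction arrows ('>' plus
#    strand, '<' minus strand).
#  - The published en dash for absent values is replaced by ASCII '-'.
#  - conservation counts informative-position matches to the box AATTGGTnnnACCAATT.
peak_position	intensity_no_effector	intensity_effector	type_printed	left_operon	left_gene	left_dir	host_gene	right_dir	right_gene	right_operon	left_function	right_function	site_sequence	conservation	motif_position	database
121966	9889	9234	A	aroP	aroP	<	-	>	pdhR	pdhR-aceEF-lpd	aromatic amino acid:H+ symporter	regulator of pyruvate dehydrogenase	AATTGGTaagACCAATT	14/14	122052	pdhR
243432	655	290	A	fadE	fadE	<	-	>	lpcA	lpcA	acyl-CoA dehydrogenase	d-sedoheptulose 7-phosphate isomerase	tccTGGTcatAgCAccT	8/14	243459	-
578844	556	239	A	ybcV	ybcV	<	-	>	ybcW	ybcW	DLP12; DUF1398 domain-containing protein	DLP12 prophage; uncharacterized protein	AtcTGGTctgACCtcTT	10/14	578887	-
1753972	555	352	A	fumD	fumD	<	-	>	pykF	pykF	fumarase D	pyruvate kinase I	AgcTGGTcagACCttTa	9/14	1753987	-
1785030	679	251	A	ppsA	ppsA	<	-	>	ppsR	ppsR	phosphoenolpyruvate synthetase	PEP synthetase regulatory protein	AgTTGGTtatACCAAag	11/14	1785098	-
2714448	6197	3323	A	grcA	grcA	<	-	>	ung	ung	stress-induced alternate pyruvate formate-lyase	uracil-DNA glycosylase	AATTGGTaaaACCAtTg	12/14	2714529	grcA
3126270	795	488	A	glcDEFGBA	glcD	<	-	>	glcC	glcC	glycolate dehydrogenase	DNA-binding transcriptional dual regulator	AATTGGTcctACCtgTg	11/14	3126271	glcD
450964	2995	2315	B	cyoABCDE	cyoA	<	-	<	ampG	-	cytochrome bo3 ubiquinol oxidase subunit 2	-	AATTGGTataACCAATg	13/14	451054	cyoA
770852	509	390	B	mngB	mngB	>	-	>	cydA	cydAB	-	cytochrome bd-I ubiquinol oxidase	tAaaGaTatgACCAAgT	9/14	770832	-
1150668	697	180	B	fabG	fabG	>	-	>	acpP	acpP-fabF	-	acyl carrier protein	AcaTGGTctgACCgctt	8/14	1150625	-
1165072	3993	4550	B	ycfP	ycfP	>	-	>	ndh	ndh	-	NADH:quinone oxidoreductase II	ttTTGGTatgACCAATg	11/14	1165180	ndh
1831272	573	99	B	xthA	xthA	>	-	>	ydjX	ydjXYZABCD	-	DedA family protein	-	-	-	-
2000362	584	87	B	fliAZ	fliA	<	-	<	fliC	-	RNA polymerase, sigma 28 (sigma F) factor	-	AAaTGGTaaaACCAcgg	10/14	2000414	-
2458466	1266	1122	B	fadIJ	fadI	<	-	<	yfcZ	-	3-ketoacyl-CoA thiolase	-	cAgcGGTaaaACCtgac	7/14	2458479	-
2839166	3469	383	B	ascF	ascF	>	-	>	ascB	ascB	-	6-phospho-beta-glucosidase	cAaaGGTctgACCAcTg	9/14	2839100	-
3775254	632	943	B	yibL	yibL	>	-	>	lldP	lldPDR	-	lactate/glycolate:H+ symporter	AATTGGccctACCAATT	13/14	3775215	-
92666	1113	114	D	ftsL	ftsL	>	ftsI	>	murE	ftsLI-murEF-mraY-murD-ftsW-murGC-ddIB-ftsQAZ-lpxC	-	UDP-N-acetylmuramoyl-l-alanyl-d-glutamate--2,6-diaminopimelate ligase	tAaTGGTaacACCAtTa	10/14	92682	-
173132	557	74	D	fhuD	fhuD	>	fhuB	<	hemL	-	-	-	-	-	-	-
435948	755	584	D	thiL	thiL	>	pgpA	<	yajO	-	-	-	AAagGaTatgACCAtTT	10/14	435814	-
480770	541	16	D	tomB-hha	tomB	<	acrB	<	acrA	-	Hha toxicity modulator	-	AAcgGaatcgACCAgcT	8/14	480940	tomB
856236	1265	1063	D	ldtB	ldtB	<	ybiT	<	ybiU	-	l,d-transpeptidase	-	AAaTGaTctgACCgtgT	9/14	856381	-
999430	1083	103	D	elfD	elfD	>	elfC	>	elfG	elfDCG-ycbUVF	-	putative fimbrial-like adhesin protein	AAaTGGTtacACCAtTT	12/14	999352	-
1412370	795	21	D	recET-ralR-rcbA-xisR-intR	ralR	<	recT	<	recE	-	Rac prophage; endodeoxyribonuclease toxin	-	-	-	-	-
1635148	820	407	D	ynfO	ynfO	>	ydfO	<	gnsB	-	-	-	AAcaGGTcagACCAgaT	10/14	1635002	-
1676572	978	128	D	pntAB	pntA	<	ydgH	>	ydgI	ydgI-folM	pyridine nucleotide transhydrogenase	putative arginine:ornithine antiporter	-	-	-	-
1738666	1142	321	D	ydhB	ydhB	<	ydhC	>	cfa	cfa	LysR family DNA-binding transcriptional regulator	cyclopropane fatty acyl phospholipid synthase	ggaTGGTctgACCttTa	8/14	1738515	-
2037932	629	65	D	yedX	yedX	>	msrP	>	msrQ	msrPQ	-	periplasmic prot-l-methionine sulfoxide reductase	AAgTGGcaaaACCAtTg	10/14	2037865	-
2075930	976	1124	D	yeeU	yeeU	>	yeeV	>	yeeW	yeeRST-cbeA-cbtA-yeeW	-	CP4-44 prophage; uncharacterized protein	-	-	-	-
2131938	2066	174	D	wcaAB	wcaA	<	wzc	<	wzb	-	colanic acid biosynthesis glycosyl transferase	-	AATTGGTaaaACCttTg	11/14	2132058	-
2317232	1633	968	D	rcsB	rcsB	>	rcsC	>	atoS	atoSC	-	sensory histidine kinase	tcagGGTatgACCAtTT	9/14	2317144	-
2517448	851	74	D	yfeD	yfeD	>	gltX	>	valU	valU	-	tRNA-Val(UAC)	tgcgGGTcttACCAATT	10/14	2517346	-
3673834	735	230	D	yhjD	yhjD	>	yhjE	<	yhjG	-	-	-	-	-	-	-
3997946	740	12	D	yigB	yigB	>	uvrD	<	yigE	-	-	-	-	-	-	-
4357756	552	484	D	cadA	cadA	<	cadB	<	cadC	-	lysine decarboxylase 1	-	tAgTGGTtaaACggcTT	9/14	4357618	-
4616836	509	216	D	deoC	deoC	>	deoA	>	deoB	deoBD	-	phosphopentomutase	cgTTaGccacgCCAAca	7/14	4616931	-
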