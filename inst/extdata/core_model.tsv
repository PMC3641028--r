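# mucaflux model tsv v1
# metadata	name	sbw25_core
# metadata	version	1
# metadata	biomass_reaction_id	BIOMASS
# metadata	maintenance_reaction_id	ATPM
# metadata	objective	BIOMASS
# metabolites
id	name	compartment	carbon_atoms
fru_e	fructose	extracellular	6
glyc_e	glycerol	extracellular	3
o2_e	oxygen	extracellular	0
co2_e	carbon dioxide	extracellular	1
nh4_e	ammonium	extracellular	0
ac_e	acetate	extracellular	2
algM_e	alginate monomer (mannuronate)	extracellular	6
algMac_e	alginate monomer, O-acetylated	extracellular	8
h2o_e	water	extracellular	0
pi_e	phosphate	extracellular	0
h_e	proton	extracellular	0
h_p	proton (periplasmic pool)	periplasm	0
f1p	fructose-1-phosphate	cytosol	6
f6p	fructose-6-phosphate	cytosol	6
fbp	fructose-1,6-bisphosphate	cytosol	6
g6p	glucose-6-phosphate	cytosol	6
pg6	6-phosphogluconate	cytosol	6
kdpg	2-keto-3-deoxy-6-phosphogluconate	cytosol	6
ru5p	ribulose-5-phosphate	cytosol	5
r5p	ribose-5-phosphate	cytosol	5
x5p	xylulose-5-phosphate	cytosol	5
s7p	sedoheptulose-7-phosphate	cytosol	7
e4p	erythrose-4-phosphate	cytosol	4
dhap	dihydroxyacetone phosphate	cytosol	3
g3p	glyceraldehyde-3-phosphate	cytosol	3
bpg13	1,3-bisphosphoglycerate	cytosol	3
pg3	3-phosphoglycerate	cytosol	3
pg2	2-phosphoglycerate	cytosol	3
pep	phosphoenolpyruvate	cytosol	3
pyr	pyruvate	cytosol	3
accoa	acetyl-CoA	cytosol	23
coa	coenzyme A	cytosol	21
actp	acetyl phosphate	cytosol	2
ac	acetate	cytosol	2
cit	citrate	cytosol	6
icit	isocitrate	cytosol	6
akg	alpha-ketoglutarate	cytosol	5
succoa	succinyl-CoA	cytosol	25
succ	succinate	cytosol	4
fum	fumarate	cytosol	4
mal	malate	cytosol	4
oaa	oxaloacetate	cytosol	4
glu	L-glutamate	cytosol	5
asp	L-aspartate	cytosol	4
glyc	glycerol	cytosol	3
glyc3p	glycerol-3-phosphate	cytosol	3
man6p	mannose-6-phosphate	cytosol	6
man1p	mannose-1-phosphate	cytosol	6
gdpman	GDP-mannose	cytosol	16
gdpmannur	GDP-mannuronate	cytosol	16
atp	ATP	cytosol	10
adp	ADP	cytosol	10
amp	AMP	cytosol	10
gtp	GTP	cytosol	10
gdp	GDP	cytosol	10
nad	NAD+	cytosol	21
nadh	NADH	cytosol	21
nadp	NADP+	cytosol	21
nadph	NADPH	cytosol	21
q	ubiquinone	cytosol	54
qh2	ubiquinol	cytosol	54
pi	phosphate	cytosol	0
ppi	pyrophosphate	cytosol	0
h	proton (cytosolic)	cytosol	0
h2o	water	cytosol	0
h2o2	hydrogen peroxide	cytosol	0
o2	oxygen	cytosol	0
co2	carbon dioxide	cytosol	1
nh4	ammonium	cytosol	0
cbiomass	biomass carbon unit	cytosol	1
# reactions
id	equation	lb	ub	gpr	subsystem
EX_fru	fru_e ->	0	1000		exchange
EX_glyc	glyc_e ->	0	1000		exchange
EX_o2	o2_e <=>	-1000	1000		exchange
EX_co2	co2_e <=>	-1000	1000		exchange
EX_nh4	nh4_e <=>	-1000	1000		exchange
EX_ac	ac_e ->	0	1000		exchange
EX_algM	algM_e ->	0	1000		exchange
EX_algMac	algMac_e ->	0	1000		exchange
EX_h2o	h2o_e <=>	-1000	1000		exchange
EX_pi	pi_e <=>	-1000	1000		exchange
EX_h	h_e <=>	-1000	1000		exchange
EX_biomass	cbiomass ->	0	1000		exchange
O2t	o2_e <=> o2	-1000	1000		transport
CO2t	co2 <=> co2_e	-1000	1000		transport
NH4t	nh4_e -> nh4	0	1000		transport
H2Ot	h2o <=> h2o_e	-1000	1000		transport
PIt	pi_e <=> pi	-1000	1000		transport
Ht	h <=> h_e	-1000	1000		transport
ACt	ac -> ac_e	0	1000		transport
FRUpts	fru_e + pep -> f1p + pyr	0	1000	fruA and fruB	fructose utilization
FRUK	f1p + atp -> fbp + adp	0	1000	fruK	fructose utilization
FBPase	fbp + h2o -> f6p + pi	0	1000	fbp	glycolysis/gluconeogenesis
PGI	g6p <=> f6p	-1000	1000	pgi	glycolysis/gluconeogenesis
G6PDH_nadp	g6p + nadp -> pg6 + nadph	0	1000	zwf1	pentose phosphate
G6PDH_nad	g6p + nad -> pg6 + nadh	0	1000	zwf2	pentose phosphate
GND	pg6 + nadp -> ru5p + co2 + nadph	0	1000	gnd	pentose phosphate
RPI	ru5p <=> r5p	-1000	1000	rpiA	pentose phosphate
RPE	ru5p <=> x5p	-1000	1000	rpe	pentose phosphate
TKT1	r5p + x5p <=> s7p + g3p	-1000	1000	tktA	pentose phosphate
TAL	s7p + g3p <=> e4p + f6p	-1000	1000	talB	pentose phosphate
TKT2	x5p + e4p <=> f6p + g3p	-1000	1000	tktA	pentose phosphate
EDD	pg6 -> kdpg + h2o	0	1000	edd	entner-doudoroff
EDA	kdpg -> g3p + pyr	0	1000	eda	entner-doudoroff
FBA	fbp <=> dhap + g3p	-1000	1000	fba	glycolysis/gluconeogenesis
TPI	dhap <=> g3p	-1000	1000	tpiA	glycolysis/gluconeogenesis
GAPD	g3p + nad + pi <=> bpg13 + nadh	-1000	1000	gap	glycolysis/gluconeogenesis
PGK	bpg13 + adp <=> pg3 + atp	-1000	1000	pgk	glycolysis/gluconeogenesis
PGM	pg3 <=> pg2	-1000	1000	gpmA	glycolysis/gluconeogenesis
ENO	pg2 <=> pep + h2o	-1000	1000	eno	glycolysis/gluconeogenesis
PYK	pep + adp -> pyr + atp	0	1000	pykA	glycolysis/gluconeogenesis
PPS	pyr + atp + h2o -> pep + amp + pi	0	1000	ppsA	glycolysis/gluconeogenesis
ADK	amp + atp <=> 2 adp	-1000	1000	adk	nucleotide interconversion
NDK	atp + gdp <=> adp + gtp	-1000	1000	ndk	nucleotide interconversion
PDH	pyr + coa + nad -> accoa + co2 + nadh	0	1000	aceE and aceF and lpdA	pyruvate metabolism
CS	accoa + oaa + h2o -> cit + coa	0	1000	gltA	tca cycle
ACONT	cit <=> icit	-1000	1000	acnB	tca cycle
ICDH	icit + nadp -> akg + co2 + nadph	0	1000	icd	tca cycle
AKGDH	akg + coa + nad -> succoa + co2 + nadh	0	1000	sucA and sucB and lpdA	tca cycle
SUCOAS	succoa + adp + pi <=> succ + atp + coa	-1000	1000	sucC and sucD	tca cycle
SUCDH	succ + q -> fum + qh2	0	1000	sdhA and sdhB	tca cycle
FUM	fum + h2o <=> mal	-1000	1000	fumC	tca cycle
MDH	mal + nad <=> oaa + nadh	-1000	1000	mdh	tca cycle
ME	mal + nadp -> pyr + co2 + nadph	0	1000	maeB	pyruvate metabolism
PYC	pyr + co2 + atp -> oaa + adp + pi	0	1000	pycA	pyruvate metabolism
PTAr	accoa + pi <=> actp + coa	-1000	1000	pta	acetate metabolism
ACKr	actp + adp <=> ac + atp	-1000	1000	ackA	acetate metabolism
GLYCt	glyc_e -> glyc	0	1000	glpF	glycerol utilization
GLYK	glyc + atp -> glyc3p + adp	0	1000	glpK	glycerol utilization
G3PD	glyc3p + q -> dhap + qh2	0	1000	glpD	glycerol utilization
PMI	f6p <=> man6p	-1000	1000	algA	alginate biosynthesis
PMM	man6p <=> man1p	-1000	1000	algC	alginate biosynthesis
GMPP	man1p + gtp -> gdpman + ppi	0	1000	algA	alginate biosynthesis
PPA	ppi + h2o -> 2 pi	0	1000	ppa	phosphate metabolism
GMD	gdpman + h2o + 2 nad -> gdpmannur + 2 nadh	0	1000	algD	alginate biosynthesis
ALGE	gdpmannur -> algM_e + gdp	0	1000	alg8 and alg44 and algE and algG and algX and algL	alginate biosynthesis
ALGEAC	gdpmannur + accoa -> algMac_e + gdp + coa	0	1000	alg8 and alg44 and algE and algI and algJ and algF	alginate biosynthesis
NDH1	nadh + q + 4 h -> nad + qh2 + 4 h_p	0	1000	nuoA and nuoB and nuoN	respiration
CYTCO	qh2 + 0.5 o2 + 6 h -> q + h2o + 6 h_p	0	1000	ccoN	respiration:cytochrome-c
CYTBD	qh2 + 0.5 o2 + 2 h -> q + h2o + 2 h_p	0	1000	cydA and cydB	respiration:ubiquinol
CYTBO	qh2 + 0.5 o2 + 2 h -> q + h2o + 2 h_p	0	1000	cyoA and cyoB	respiration:ubiquinol
ATPS	adp + pi + 4 h_p -> atp + h2o + 4 h	0	1000	atpA and atpD	respiration
AATB	glu + oaa -> asp + akg	0	1000	aatB	nadph cycle
KATB	h2o2 -> h2o + 0.5 o2	0	1000	katB	nadph cycle
GDHA	akg + nh4 + nadph + h -> glu + nadp + h2o	0	1000	gdhA	nadph cycle
NADB	asp + o2 + h2o -> nh4 + h2o2 + oaa	0	1000	nadB	nadph cycle
ATPM	atp + h2o -> adp + pi	0	1000		maintenance
BIOMASS	6 pyr + 2 oaa + 1.45 akg + 0.5 f6p + 0.5 g3p + 9 nh4 + 12 nadph + 43 atp + 43 h2o -> 12 nadp + 43 adp + 43 pi + 37.75 cbiomass	0	1000		biomass
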