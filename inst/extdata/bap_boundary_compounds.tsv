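# Boundary compounds of the BAp metabolic network (inputs = required imports,
# outputs = required exports) with compound class and passive-diffusion flag.
compound	name	class	direction	diffusion
Ala	alanine	amino_acid	import	0
Asp	aspartate	amino_acid	import	0
Asn	asparagine	amino_acid	import	0
Glu	glutamate	amino_acid	import	0
Gln	glutamine	amino_acid	import	0
homocysteine	homocysteine	amino_acid	import	0
Pro	proline	amino_acid	import	0
Ser	serine	amino_acid	import	0
Gly	glycine	amino_acid	import	0
Tyr	tyrosine	amino_acid	import	0
Val	valine	amino_acid	import	0
Leu	leucine	amino_acid	import	0
Ile	isoleucine	amino_acid	import	0
2-oxobutanoate	2-oxobutanoate	organic_acid	import	0
putrescine	putrescine	organic_acid	import	0
guanosine	guanosine	nucleotide_or_derivative	import	0
inosine	inosine	nucleotide_or_derivative	import	0
glucose	D-glucose	sugar_or_derivative	import	0
mannitol	D-mannitol	sugar_or_derivative	import	0
cobalamin	vitamin B12	vitamin_or_cofactor	import	0
dihydropteroate	7,8-dihydropteroate	vitamin_or_cofactor	import	0
nicotinate	vitamin B3	vitamin_or_cofactor	import	0
pantetheine-4P	pantetheine 4-phosphate	vitamin_or_cofactor	import	0
pyridoxine	vitamin B6	vitamin_or_cofactor	import	0
thiamine	vitamin B1	vitamin_or_cofactor	import	0
ubiquinol	ubiquinol	vitamin_or_cofactor	import	0
uroporphyrinogen-III	uroporphyrinogen III	vitamin_or_cofactor	import	0
protoheme	protoheme	vitamin_or_cofactor	import	0
7-keto-8-aminopelargonate	biotin precursor	misc	import	0
malonyl-CoA	malonyl-CoA	misc	import	0
L1-phosphatidyl-glycerol	L1-phosphatidylglycerol	lipid	import	0
phosphate	inorganic phosphate	ion	import	0
zinc	Zn2+	ion	import	0
magnesium	Mg2+	ion	import	0
iron	Fe2+/Fe3+	ion	import	0
potassium	K+	ion	import	0
CO2	carbon dioxide	small_solute	import	1
O2	oxygen	small_solute	import	1
H2O	water	small_solute	import	1
NH3	ammonia	small_solute	import	1
glycerol	glycerol	small_solute	import	1
formaldehyde	formaldehyde	small_solute	import	1
2-keto-3-methylvalerate	2-keto-3-methylvalerate	organic_acid	export	0
2-ketoisovalerate	2-ketoisovalerate	organic_acid	export	0
2-ketoisocaproate	2-ketoisocaproate	organic_acid	export	0
phenylpyruvate	phenylpyruvate	organic_acid	export	0
fumarate	fumarate	organic_acid	export	0
succinate	succinate	organic_acid	export	0
spermidine	spermidine	organic_acid	export	0
Arg	arginine	amino_acid	export	0
Cys	cysteine	amino_acid	export	0
His	histidine	amino_acid	export	0
Lys	lysine	amino_acid	export	0
Thr	threonine	amino_acid	export	0
Trp	tryptophan	amino_acid	export	0
adenine	adenine	nucleotide_or_derivative	export	0
biotin	vitamin B7	vitamin_or_cofactor	export	0
riboflavin	vitamin B2	vitamin_or_cofactor	export	0
ADP-glycero-mannoheptulose	ADP-D-glycero-D-manno-heptulose	lipid	export	0
outer-membrane-proteins	outer membrane proteins	peptide_or_protein	export	0
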