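# Biomarker metabolites reported for schizophrenia (SCZ) and bipolar disorder (BD).
# 47 rows; "acetate" appears once per disease, so 46 unique metabolites
# (28 SCZ, 25 BD, 7 common).  The published list does not give per-metabolite
# disease labels beyond those totals; label assignments here are a synthetic
# reconstruction consistent with the totals.
metabolite	disease_label
acetate	SCZ
N-acetyl-d-mannosamine	SCZ
2,3-diphospho-d-glyceric-acid	SCZ
alpha-ketoglutaric-acid	SCZ
N-acetyl-l-alanine	SCZ
arginine	SCZ
choline	SCZ
formate	SCZ
glutamate	SCZ
amygdalin	SCZ
isocitric acid	SCZ
myo-inositol	SCZ
N-acetyl-glutamic-acid	SCZ
phenylalanine	SCZ
propionate	SCZ
pyruvate	SCZ
serine	SCZ
beta-alanine	SCZ
N-acetyl-l-phenyl-alanine	SCZ
lipoamide	SCZ
alpha-ketoisovaleric acid	SCZ
l-glutamine	SCZ
acetate	BD
N-acetyl aspartyl-glutamic acid	BD
lactate	BOTH
phosphocholine	BD
alanine	BOTH
citrate	BD
cystine	BD
eicosanoic acid	BD
glucose	BOTH
glycerate	BD
beta-hydroxybutyrate	BD
pyroglutamic acid	BD
sorbitol	BD
taurine	BOTH
tocopherol-alpha	BD
uridine	BD
l-threonine	BD
adenine	BD
glycine	BOTH
adenosine	BD
GABA	BOTH
mannitol	BD
pantothenate	BD
3-methyl-2-oxobutinoic acid	BD
guanine	BD
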