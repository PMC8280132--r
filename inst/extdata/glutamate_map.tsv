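# Synthetic emulation of a partial l-glutamate metabolic map: compound nodes
# joined by enzyme-labelled edges (one row per edge-label pair).  Four
# branches leave l-glutamate; the twelve enzymes on the first two shells of
# edges lie within path length 2 of l-glutamate, while CPS1 and ALDH5A1 sit
# on third-shell edges and are beyond it.
compound_a	compound_b	enzyme_label
l-glutamate	2-oxoglutarate	GLUD1
l-glutamate	2-oxoglutarate	GLUD2
2-oxoglutarate	2-oxoglutaramate	NIT2
l-glutamate	l-glutamate-5-semialdehyde	ALDH4A1
l-glutamate	gamma-aminobutyric-acid	GAD1
gamma-aminobutyric-acid	succinate-semialdehyde	ABAT
succinate-semialdehyde	succinate	ALDH5A1
l-glutamate	l-glutamine	GLUL
l-glutamate	l-glutamine	GLS
l-glutamate	l-glutamine	GLS2
l-glutamine	d-glucosamine-6-phosphate	GFPT1
l-glutamine	d-glucosamine-6-phosphate	GFPT2
l-glutamine	5-phosphoribosylamine	PPAT
2-oxoglutaramate	carbamoyl-phosphate	CPS1
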