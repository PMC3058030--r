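metal	pattern	note
Co	cobalt	elemental name
Co	cobalamin|corrin(oid)?|\bB12\b	cobalamin/corrinoid cofactors
Fe	\biron\b|ferric|ferrous	elemental name and ion adjectives
Fe	ferredoxin|ferritin|\bheme\b|\bhaem\b|hemery|siderophore	iron cofactors and carriers
Fe	iron[- ]sulfur|\bFe[- ]?S\b|\[\s*[0-9]Fe[- ][0-9]S\s*\]	iron-sulfur clusters
Mn	manganese	elemental name
Mo	molybd	molybdenum, molybdate, molybdopterin
Ni	nickel	elemental name
Ni	urease|\[NiFe\]	canonical Ni enzymes/centres
Pb	\blead(\(II\)| ?ions?| binding| resistance)	lead the metal, not the verb
Pb	plumb(ous|ic)	ion adjectives
U	uranium|uranyl	elemental name and ion
V	vanad	vanadium, vanadate, vanadyl
W	tungst	tungsten, tungstate, tungstopterin
W	\bW[- ]?cofactor	tungsten cofactor shorthand
W	molybdopterin	tungstoenzymes bind W through the molybdopterin cofactor
Zn	\bzinc	elemental name
Zn	\bZn[- ]?finger|zinc[- ]finger	zinc finger domains
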