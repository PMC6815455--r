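fragment	note
C	methyl/methylene unit
CC	ethylene unit
CCC	propylene unit
C(C)C	isopropyl branch
C(C)(C)C	quaternary branch
O	ether oxygen
CO	hydroxymethyl/ether
OC	ether linkage
N	amine nitrogen
CN	aminomethyl
NC	amine linkage
C=C	vinylene
CS	thioether
c1ccccc1	benzene ring
Cc1ccccc1	toluyl
c1ccncc1	pyridine ring
c1ccsc1	thiophene ring
C1CCCCC1	cyclohexane ring
C(=O)O	carboxyl/ester
C(=O)N	amide (default activity motif)
C(=O)C	ketone
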